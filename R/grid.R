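#' Global grid specification
#'
#' Defines the global longitude/latitude grid on which all stressor layers,
#' range rasterizations and aggregation maps live. The default is the
#' 0.5-degree grid (720 x 360 cells). Cells are indexed row-major from the
#' north-west corner and are half-open in both axes: a cell at column `c`,
#' row `r` covers longitudes `[lon0, lon0 + res)` and latitudes
#' `(lat1 - res, lat1]`, so every point with `lon` in `[-180, 180)` and
#' `lat` in `(-90, 90]` belongs to exactly one cell.
#'
#' @param resolution Cell size in degrees; must divide 360 evenly.
#' @return An object of class `pe_grid` with fields `resolution`, `n_cols`,
#'   `n_rows`, `n_cells`.
#' @export
grid_spec <- function(resolution = 0.5) {
  if (!is.numeric(resolution) || length(resolution) != 1L ||
      !is.finite(resolution) || resolution <= 0 ||
      abs(360 / resolution - round(360 / resolution)) > 1e-9) {
    stop("`resolution` must be a positive number that divides 360 evenly",
         call. = FALSE)
  }
  n_cols <- as.integer(round(360 / resolution))
  n_rows <- as.integer(round(180 / resolution))
  structure(
    list(resolution = resolution,
         lon_min = -180, lon_max = 180, lat_min = -90, lat_max = 90,
         n_cols = n_cols, n_rows = n_rows, n_cells = n_cols * n_rows),
    class = "pe_grid")
}

#' @export
print.pe_grid <- function(x, ...) {
  cat(sprintf("<pe_grid> %.3g deg, %d x %d = %d cells (row-major, NW origin)\n",
              x$resolution, x$n_rows, x$n_cols, x$n_cells))
  invisible(x)
}

is_grid <- function(x) inherits(x, "pe_grid")

assert_grid <- function(grid) {
  if (!is_grid(grid)) stop("not a `pe_grid` object", call. = FALSE)
  invisible(grid)
}

#' Map coordinates to grid cells
#'
#' Applies the half-open binning convention: column `floor((lon+180)/res)`,
#' row `floor((90-lat)/res)` (0-based), converted to 1-based row-major cell
#' ids. A point with `lon = 0.5` at 0.5-degree resolution falls in the cell
#' whose left edge is 0.5.
#'
#' @param lon,lat Numeric vectors of equal length, `lon` in `[-180, 180)`,
#'   `lat` in `(-90, 90]`.
#' @param grid A [grid_spec()].
#' @return Integer vector of cell ids in `1..n_cells`.
#' @export
cell_of <- function(lon, lat, grid) {
  assert_grid(grid)
  stopifnot(length(lon) == length(lat))
  bad <- which(!is.finite(lon) | !is.finite(lat) |
                 lon < -180 | lon >= 180 | lat <= -90 | lat > 90)
  if (length(bad)) {
    stop(sprintf("coordinates out of range at point index %s",
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  res <- grid$resolution
  col <- floor((lon + 180) / res)                 # 0-based
  row <- floor((90 - lat) / res)
  # lat == 90 - k*res for integer k sits on a cell top edge and belongs to
  # that cell (half-open at the bottom); floor already does this except for
  # the exact top of the grid handled by the range check above.
  row[row == grid$n_rows] <- grid$n_rows - 1     # lat == -90 excluded above; guard fp
  col[col == grid$n_cols] <- grid$n_cols - 1
  as.integer(row * grid$n_cols + col + 1)
}

#' Cell bounding rectangles
#'
#' @param cells Integer cell ids.
#' @param grid A [grid_spec()].
#' @return A data.frame with `cell`, `row`, `col` (1-based), `lon0`, `lon1`,
#'   `lat0`, `lat1`; the cell covers `[lon0, lon1)` x `(lat0, lat1]`.
#' @export
cell_bounds <- function(cells, grid) {
  assert_grid(grid)
  cells <- as.integer(cells)
  if (any(cells < 1L | cells > grid$n_cells)) {
    stop("cell id out of range", call. = FALSE)
  }
  row <- (cells - 1L) %/% grid$n_cols + 1L
  col <- (cells - 1L) %% grid$n_cols + 1L
  res <- grid$resolution
  lon0 <- -180 + (col - 1L) * res
  lat1 <- 90 - (row - 1L) * res
  data.frame(cell = cells, row = row, col = col,
             lon0 = lon0, lon1 = lon0 + res,
             lat0 = lat1 - res, lat1 = lat1)
}

#' Cell center coordinates
#' @inheritParams cell_bounds
#' @return data.frame with `cell`, `lon`, `lat` of cell centers.
#' @export
cell_centers <- function(cells, grid) {
  b <- cell_bounds(cells, grid)
  data.frame(cell = b$cell, lon = (b$lon0 + b$lon1) / 2,
             lat = (b$lat0 + b$lat1) / 2)
}

#' View a cell-indexed value vector as a matrix
#'
#' @param values Numeric vector of length `grid$n_cells` in row-major order.
#' @param grid A [grid_spec()].
#' @return An `n_rows` x `n_cols` matrix, row 1 = northernmost band.
#' @export
as_grid_matrix <- function(values, grid) {
  assert_grid(grid)
  stopifnot(length(values) == grid$n_cells)
  matrix(values, nrow = grid$n_rows, ncol = grid$n_cols, byrow = TRUE)
}

#' @rdname as_grid_matrix
#' @param m A matrix as returned by [as_grid_matrix()].
#' @export
as_grid_vector <- function(m, grid) {
  assert_grid(grid)
  stopifnot(nrow(m) == grid$n_rows, ncol(m) == grid$n_cols)
  as.vector(t(m))
}

#' Construct a stressor layer
#'
#' @param name Layer name.
#' @param values Numeric vector of length `grid$n_cells` (NA allowed).
#' @param kind One of `"autocorrelated"`, `"noise"`, `"count-like"`.
#' @param grid A [grid_spec()].
#' @return Object of class `pe_layer`.
#' @export
stressor_layer <- function(name, values, kind, grid) {
  assert_grid(grid)
  kind <- match.arg(kind, c("autocorrelated", "noise", "count-like"))
  if (length(values) != grid$n_cells) {
    stop("layer dimensions do not match the grid", call. = FALSE)
  }
  if (kind == "count-like") {
    v <- values[!is.na(values)]
    if (any(v < 0) || any(v != round(v))) {
      stop("count-like layers must hold non-negative integers", call. = FALSE)
    }
  }
  structure(list(name = name, values = as.numeric(values), kind = kind),
            class = "pe_layer")
}

#' @export
print.pe_layer <- function(x, ...) {
  cat(sprintf("<pe_layer> '%s' (%s), %d cells, %d NA\n", x$name, x$kind,
              length(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' Lag-1 spatial autocorrelation of a layer
#'
#' A Moran-style statistic: the Pearson correlation between values of
#' rook-adjacent cell pairs (horizontal and vertical neighbours pooled).
#' Near zero for white noise, positive for smoothed fields.
#'
#' @param values Cell-value vector or a `pe_layer`.
#' @param grid A [grid_spec()].
#' @return A single correlation in `[-1, 1]`.
#' @export
moran_lag1 <- function(values, grid) {
  if (inherits(values, "pe_layer")) values <- values$values
  m <- as_grid_matrix(values, grid)
  nr <- nrow(m); nc <- ncol(m)
  a <- c(m[, -nc], m[-nr, ])
  b <- c(m[, -1], m[-1, ])
  ok <- !is.na(a) & !is.na(b)
  stats::cor(a[ok], b[ok])
}
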