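# Feature extraction: range rasterization, occurrence binning, zonal
# statistics and assembly of the species x predictor table.

#' Rasterize a species range onto the grid
#'
#' Unions all native + extant seasonal polygons of a species and returns the
#' ids of every grid cell whose rectangle intersects any polygon with
#' positive area (not a center-in rule: small-range species must not vanish
#' from the grid). If no cell qualifies, the cell containing the centroid of
#' the largest polygon is returned, so the result is never empty.
#'
#' @param polygons A list of range polygons; each element is a list with
#'   `coords` (two-column lon/lat vertex matrix), `seasonal`, `presence`,
#'   `origin`. Polygons whose `origin` is not `"native"` or whose `presence`
#'   is not `"extant"` are ignored.
#' @param grid A [grid_spec()].
#' @param method `"bands"` (fast row-band scan, exact for convex polygons;
#'   non-convex polygons automatically fall back to `"exhaustive"`) or
#'   `"exhaustive"` (per-cell clipping over the bounding box).
#' @return Sorted integer vector of cell ids (never empty).
#' @export
rasterize_range <- function(polygons, grid, method = c("bands", "exhaustive")) {
  assert_grid(grid)
  method <- match.arg(method)
  keep <- vapply(polygons, function(p) {
    identical(p$origin, "native") && identical(p$presence, "extant")
  }, logical(1))
  if (!any(keep)) {
    stop("species has no native + extant range polygon", call. = FALSE)
  }
  polys <- lapply(polygons[keep], `[[`, "coords")
  cells <- integer(0)
  for (poly in polys) {
    use_bands <- method == "bands" && is_convex_polygon(poly)
    cells <- c(cells, if (use_bands) cells_bands(poly, grid)
               else cells_exhaustive(poly, grid))
  }
  cells <- sort(unique(cells))
  if (length(cells) == 0L) {
    areas <- vapply(polys, polygon_area, numeric(1))
    ctr <- polygon_centroid(polys[[which.max(areas)]])
    lon <- min(max(ctr[1], -180), 180 - 1e-9)
    lat <- min(max(ctr[2], -90 + 1e-9), 90)
    cells <- cell_of(lon, lat, grid)
  }
  cells
}

# Row-band scan: clip the (convex) polygon to each grid latitude band; the
# band slice is convex, so every cell whose open x-interval overlaps the
# slice's x-extent has a positive-area intersection.
cells_bands <- function(poly, grid, eps = 1e-12) {
  res <- grid$resolution
  ymin <- max(min(poly[, 2]), -90)
  ymax <- min(max(poly[, 2]), 90)
  if (ymax - ymin <= eps) return(integer(0))
  r0 <- max(1L, floor((90 - ymax) / res) + 1L)
  r1 <- min(grid$n_rows, ceiling((90 - ymin) / res))
  out <- vector("list", r1 - r0 + 1L)
  for (r in r0:r1) {
    top <- 90 - (r - 1L) * res
    bot <- top - res
    slice <- clip_halfplane(poly, 2L, bot, keep_ge = TRUE)
    slice <- clip_halfplane(slice, 2L, top, keep_ge = FALSE)
    if (nrow(slice) < 3L || polygon_area(slice) <= eps) next
    x0 <- max(min(slice[, 1]), -180)
    x1 <- min(max(slice[, 1]), 180)
    if (x1 - x0 <= eps) next
    c0 <- max(1L, floor((x0 + 180) / res - eps) + 1L)
    c1 <- min(grid$n_cols, ceiling((x1 + 180) / res + eps))
    # trim end columns whose overlap with the slice has no width
    while (c0 <= c1 && (-180 + c0 * res) - x0 <= eps) c0 <- c0 + 1L
    while (c1 >= c0 && x1 - (-180 + (c1 - 1L) * res) <= eps) c1 <- c1 - 1L
    if (c0 > c1) next
    out[[r - r0 + 1L]] <- (r - 1L) * grid$n_cols + (c0:c1)
  }
  as.integer(unlist(out))
}

# Exhaustive scan of the bounding box with per-cell clipped-area test.
cells_exhaustive <- function(poly, grid, eps = 1e-12) {
  res <- grid$resolution
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  c0 <- max(1L, floor((max(xr[1], -180) + 180) / res) + 1L)
  c1 <- min(grid$n_cols, floor((min(xr[2], 180 - 1e-12) + 180) / res) + 1L)
  r0 <- max(1L, floor((90 - min(yr[2], 90 - 1e-12)) / res) + 1L)
  r1 <- min(grid$n_rows, floor((90 - max(yr[1], -90 + 1e-12)) / res) + 1L)
  if (c0 > c1 || r0 > r1) return(integer(0))
  hits <- integer(0)
  for (r in r0:r1) {
    top <- 90 - (r - 1L) * res
    for (cc in c0:c1) {
      lon0 <- -180 + (cc - 1L) * res
      a <- rect_intersection_area(poly, lon0, lon0 + res, top - res, top)
      if (a > eps) hits <- c(hits, (r - 1L) * grid$n_cols + cc)
    }
  }
  hits
}

#' Bin occurrence points into grid cells
#'
#' @param points A data.frame with columns `lon`, `lat` (degrees). Duplicate
#'   points collapse in the cell set but all count in `n_points`.
#' @param grid A [grid_spec()].
#' @return List with `n_points` (integer) and `cells` (sorted unique ids).
#' @export
occurrence_cells <- function(points, grid) {
  assert_grid(grid)
  if (is.null(points) || nrow(points) == 0L) {
    return(list(n_points = 0L, cells = integer(0)))
  }
  ids <- cell_of(points$lon, points$lat, grid)
  list(n_points = nrow(points), cells = sort(unique(ids)))
}

#' Zonal summary of a layer over a cell set
#'
#' Min, max, mean and median of the layer's non-missing values over `cells`.
#' If every value is missing, all four statistics are `NA` (the summary is
#' "missing", to be imputed downstream). The median of an even count is the
#' mean of the two middle values.
#'
#' @param layer A [stressor_layer()] (or plain value vector).
#' @param cells Non-empty integer cell ids.
#' @return Named list `min`, `max`, `mean`, `median`.
#' @export
zonal_stats <- function(layer, cells) {
  values <- if (inherits(layer, "pe_layer")) layer$values else layer
  if (length(cells) == 0L) {
    stop("zonal_stats requires a non-empty cell set", call. = FALSE)
  }
  v <- values[cells]
  v <- v[!is.na(v)]
  if (length(v) == 0L) {
    return(list(min = NA_real_, max = NA_real_,
                mean = NA_real_, median = NA_real_))
  }
  list(min = min(v), max = max(v), mean = mean(v),
       median = stats::median(v))
}

#' Sum a count-like layer over a range
#'
#' Analogue of counting dams / power plants falling inside a species range:
#' the sum of per-cell counts over the range cells (missing cells count 0).
#'
#' @param point_layer A count-like [stressor_layer()].
#' @param cells Integer cell ids.
#' @return Non-negative integer sum.
#' @export
count_points_in_range <- function(point_layer, cells) {
  if (!inherits(point_layer, "pe_layer") || point_layer$kind != "count-like") {
    stop("`point_layer` must be a count-like stressor layer", call. = FALSE)
  }
  v <- point_layer$values[cells]
  v <- v[!is.na(v)]
  if (any(v < 0)) stop("negative counts in count-like layer", call. = FALSE)
  as.integer(sum(v))
}

#' Assemble the species x predictor feature table
#'
#' One row per retained species (EX/EW dropped), sorted by `species_id` so
#' the result is invariant to input order. Occurrence-derived columns are
#' missing (`NA`), not zero, for species without occurrence points; they are
#' filled later by [impute_missing()]. Zonal summaries of every non-count
#' layer are computed over both supports (range cells and occurrence cells),
#' four statistics each; count-like layers contribute one range-sum column.
#'
#' @param species Species table (one row per species) with columns
#'   `species_id`, `kingdom`, `phylum`, `class`, `family`, `category`,
#'   `terrestrial`, `freshwater`, `marine`, `n_habitats`, `n_subhabitats`,
#'   `n_major_habitats`, `outdated_assessment`.
#' @param occurrences data.frame `species_id`, `lon`, `lat`, `year`.
#' @param layers List of [stressor_layer()]s.
#' @param grid A [grid_spec()].
#' @param ranges Named list (by species_id) of polygon lists, used when
#'   `range_cells` is not supplied.
#' @param range_cells Optional named list (by species_id) of precomputed
#'   range cell ids.
#' @return A data.frame of class `pe_features` with attributes
#'   `column_manifest` (name, source_layer, statistic, support) and
#'   `range_cells`. Column `label` is `"threatened"` / `"not_threatened"`
#'   / `NA` (DD held out).
#' @export
assemble_feature_table <- function(species, occurrences, layers, grid,
                                   ranges = NULL, range_cells = NULL) {
  assert_grid(grid)
  sp <- species[order(species$species_id), , drop = FALSE]
  lab <- binarize_category(sp$category)
  drop <- lab == "excluded"
  if (any(drop)) {
    message(sprintf("dropping %d EX/EW species from the feature table",
                    sum(drop)))
    sp <- sp[!drop, , drop = FALSE]
    lab <- lab[!drop]
  }
  ids <- sp$species_id
  if (anyDuplicated(ids)) stop("duplicated species_id", call. = FALSE)

  if (is.null(range_cells)) {
    if (is.null(ranges)) stop("need `ranges` or `range_cells`", call. = FALSE)
    missing_ids <- setdiff(ids, names(ranges))
    if (length(missing_ids)) {
      stop(sprintf("no range geometry for species: %s",
                   paste(utils::head(missing_ids, 5L), collapse = ", ")),
           call. = FALSE)
    }
    range_cells <- lapply(ranges[ids], rasterize_range, grid = grid)
  } else {
    missing_ids <- setdiff(ids, names(range_cells))
    if (length(missing_ids)) {
      stop(sprintf("no range cells for species: %s",
                   paste(utils::head(missing_ids, 5L), collapse = ", ")),
           call. = FALSE)
    }
    range_cells <- range_cells[ids]
  }

  occ_split <- if (nrow(occurrences)) split(occurrences, occurrences$species_id)
               else list()
  unknown <- setdiff(names(occ_split), species$species_id)
  if (length(unknown)) {
    stop(sprintf("occurrences reference unknown species: %s",
                 paste(utils::head(unknown, 5L), collapse = ", ")),
         call. = FALSE)
  }

  is_count <- vapply(layers, function(l) l$kind == "count-like", logical(1))
  zonal_layers <- layers[!is_count]
  count_layers <- layers[is_count]
  layer_mat <- if (length(zonal_layers))
    vapply(zonal_layers, `[[`, numeric(grid$n_cells), "values") else NULL
  stat_names <- c("min", "max", "mean", "median")

  n <- length(ids)
  range_extent_cells <- lengths(range_cells)
  range_km2 <- numeric(n)
  n_occ_points <- integer(n)
  n_occ_cells <- rep(NA_integer_, n)
  zr <- matrix(NA_real_, n, length(zonal_layers) * 4L)
  zo <- matrix(NA_real_, n, length(zonal_layers) * 4L)
  cnt <- matrix(NA_real_, n, length(count_layers))

  if (!is.null(ranges)) {
    for (i in seq_len(n)) {
      polys <- ranges[[ids[i]]]
      keep <- vapply(polys, function(p) {
        identical(p$origin, "native") && identical(p$presence, "extant")
      }, logical(1))
      range_km2[i] <- sum(vapply(polys[keep], function(p)
        polygon_area_km2(clip_world(p$coords)), numeric(1)))
    }
  } else {
    # geometry unavailable: approximate geodesic extent from cell areas
    for (i in seq_len(n)) {
      b <- cell_bounds(range_cells[[i]], grid)
      range_km2[i] <- sum(cell_area_km2(b))
    }
  }

  for (i in seq_len(n)) {
    rc <- range_cells[[i]]
    if (!is.null(layer_mat)) {
      zr[i, ] <- zonal_row(layer_mat, rc)
    }
    if (length(count_layers)) {
      cnt[i, ] <- vapply(count_layers, count_points_in_range,
                         integer(1), cells = rc)
    }
    occ <- occ_split[[ids[i]]]
    if (!is.null(occ) && nrow(occ)) {
      oc <- occurrence_cells(occ, grid)
      n_occ_points[i] <- oc$n_points
      n_occ_cells[i] <- length(oc$cells)
      if (!is.null(layer_mat)) zo[i, ] <- zonal_row(layer_mat, oc$cells)
    } else {
      n_occ_points[i] <- 0L   # zero points is observed, derived stats are not
    }
  }

  zname <- function(support) {
    unlist(lapply(zonal_layers, function(l)
      paste(l$name, support, stat_names, sep = "_")))
  }
  colnames(zr) <- zname("range")
  colnames(zo) <- zname("occ")
  if (length(count_layers)) {
    colnames(cnt) <- paste0("n_", vapply(count_layers, `[[`, "", "name"))
  }

  tab <- data.frame(
    species_id = ids,
    kingdom = sp$kingdom, phylum = sp$phylum, class = sp$class,
    family = sp$family,
    dom_terrestrial = as.integer(sp$terrestrial),
    dom_freshwater = as.integer(sp$freshwater),
    dom_marine = as.integer(sp$marine),
    n_habitats = sp$n_habitats,
    n_subhabitats = sp$n_subhabitats,
    n_major_habitats = sp$n_major_habitats,
    n_native_countries = sp$n_native_countries,
    range_cells = as.integer(range_extent_cells),
    range_km2 = range_km2,
    n_occurrence_points = n_occ_points,
    n_occurrence_cells = n_occ_cells,
    stringsAsFactors = FALSE)
  if (length(count_layers)) tab <- cbind(tab, as.data.frame(cnt))
  tab <- cbind(tab, as.data.frame(zr), as.data.frame(zo))
  tab$label <- ifelse(lab == "dd", NA_character_, lab)
  rownames(tab) <- NULL

  manifest <- column_manifest(tab, zonal_layers, count_layers)
  structure(tab, column_manifest = manifest,
            range_cells = range_cells,
            class = c("pe_features", "data.frame"))
}

zonal_row <- function(layer_mat, cells) {
  m <- layer_mat[cells, , drop = FALSE]
  nl <- ncol(m)
  out <- numeric(nl * 4L)
  for (k in seq_len(nl)) {
    v <- m[, k]
    v <- v[!is.na(v)]
    o <- (k - 1L) * 4L
    if (length(v)) {
      out[o + 1L] <- min(v); out[o + 2L] <- max(v)
      out[o + 3L] <- mean(v); out[o + 4L] <- stats::median(v)
    } else {
      out[o + (1:4)] <- NA_real_
    }
  }
  out
}

cell_area_km2 <- function(b) {
  r <- 6371.0072
  dlon <- (b$lon1 - b$lon0) * pi / 180
  r^2 * dlon * abs(sin(b$lat1 * pi / 180) - sin(b$lat0 * pi / 180))
}

clip_world <- function(poly) {
  if (min(poly[, 1]) >= -180 && max(poly[, 1]) <= 180 &&
      min(poly[, 2]) >= -90 && max(poly[, 2]) <= 90) return(poly)
  p <- clip_polygon_rect(poly, -180, 180, -90, 90)
  if (nrow(p) < 3L) poly else p
}

column_manifest <- function(tab, zonal_layers, count_layers) {
  nm <- names(tab)
  man <- data.frame(name = nm, source_layer = NA_character_,
                    statistic = NA_character_, support = NA_character_,
                    stringsAsFactors = FALSE)
  for (l in zonal_layers) {
    for (support in c("range", "occ")) {
      for (s in c("min", "max", "mean", "median")) {
        i <- match(paste(l$name, support, s, sep = "_"), nm)
        man$source_layer[i] <- l$name
        man$statistic[i] <- s
        man$support[i] <- if (support == "range") "range_cells" else
          "occurrence_cells"
      }
    }
  }
  for (l in count_layers) {
    i <- match(paste0("n_", l$name), nm)
    man$source_layer[i] <- l$name
    man$statistic[i] <- "sum"
    man$support[i] <- "range_cells"
  }
  man
}

#' Fit a random-draw imputer on training rows
#'
#' Each numeric column's pool of observed training values is stored; missing
#' entries anywhere are later replaced by seeded uniform draws from the
#' training pool (the classical "impute with random observed values"
#' scheme). Columns with no observed training value are dropped with a
#' warning.
#'
#' @param table A feature table.
#' @param train_ids Species ids defining the training rows (default: all).
#' @return An object of class `pe_imputer`.
#' @export
make_imputer <- function(table, train_ids = NULL) {
  rows <- if (is.null(train_ids)) seq_len(nrow(table)) else
    which(table$species_id %in% train_ids)
  num <- names(table)[vapply(table, is.numeric, logical(1))]
  pools <- list(); dropped <- character(0)
  for (cn in num) {
    v <- table[[cn]][rows]
    v <- v[!is.na(v)]
    if (length(v) == 0L) dropped <- c(dropped, cn) else pools[[cn]] <- v
  }
  if (length(dropped)) {
    warning(sprintf("dropping all-missing column(s): %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
  }
  structure(list(pools = pools, dropped = dropped), class = "pe_imputer")
}

#' Apply a fitted imputer
#'
#' @param imputer A [make_imputer()] result.
#' @param table Feature table (training, test or DD rows).
#' @param seed Integer seed for the draws.
#' @return The table with missing numeric entries filled from the training
#'   pools and dropped columns removed. Observed entries are untouched.
#' @export
apply_imputer <- function(imputer, table, seed) {
  stopifnot(inherits(imputer, "pe_imputer"))
  with_seed(stage_seed(seed, "impute"), {
    for (cn in names(imputer$pools)) {
      if (!cn %in% names(table)) next
      miss <- which(is.na(table[[cn]]))
      if (length(miss)) {
        table[[cn]][miss] <- sample(imputer$pools[[cn]], length(miss),
                                    replace = TRUE)
      }
    }
  })
  for (cn in imputer$dropped) table[[cn]] <- NULL
  table
}

#' Impute missing feature values with random observed values
#'
#' Convenience wrapper: fits the imputer on `train_ids` (all rows by
#' default) and applies it to the whole table.
#'
#' @inheritParams make_imputer
#' @param seed Integer seed.
#' @return Imputed table (same class/attributes).
#' @export
impute_missing <- function(table, seed, train_ids = NULL) {
  imp <- make_imputer(table, train_ids)
  out <- apply_imputer(imp, table, seed)
  attributes_keep(out, table)
}

attributes_keep <- function(out, template) {
  for (a in c("column_manifest", "range_cells")) {
    attr(out, a) <- attr(template, a)
  }
  class(out) <- class(template)
  out
}

#' One-hot encode a feature table into a numeric model matrix
#'
#' Categorical columns (kingdom, phylum, class) expand into 0/1 indicator
#' blocks; `family` and bookkeeping columns are excluded from the predictor
#' set. The block map ties each matrix column back to its source feature so
#' shadow-feature selection can confirm whole blocks.
#'
#' @param table A feature table.
#' @return List with `x` (numeric matrix, rownames = species_id), `blocks`
#'   (character vector: source feature per column) and `ids`.
#' @export
encode_features <- function(table) {
  excl <- c("species_id", "family", "label")
  cols <- setdiff(names(table), excl)
  parts <- list(); blocks <- character(0)
  for (cn in cols) {
    v <- table[[cn]]
    if (is.numeric(v)) {
      m <- matrix(v, ncol = 1, dimnames = list(NULL, cn))
      parts[[cn]] <- m
      blocks <- c(blocks, cn)
    } else {
      lev <- sort(unique(as.character(v)))
      m <- vapply(lev, function(l) as.numeric(v == l),
                  numeric(length(v)))
      if (length(v) == 1L) m <- matrix(m, nrow = 1)
      colnames(m) <- paste(cn, lev, sep = ".")
      parts[[cn]] <- m
      blocks <- c(blocks, rep(cn, length(lev)))
    }
  }
  x <- do.call(cbind, parts)
  rownames(x) <- table$species_id
  list(x = x, blocks = blocks, ids = table$species_id)
}
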