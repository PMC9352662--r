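# Planar polygon utilities in lon/lat degree space. Range polygons are
# simple (non-self-intersecting) rings stored as two-column matrices
# (lon, lat), not closed (first vertex not repeated).

#' Axis-aligned ellipse polygon
#'
#' @param center_lon,center_lat Ellipse center in degrees.
#' @param semi_lon,semi_lat Semi-axes in degrees (longitude / latitude).
#' @param n_vertices Number of vertices of the polygonal approximation.
#' @return Two-column matrix of (lon, lat) vertices, counter-clockwise.
#' @export
ellipse_polygon <- function(center_lon, center_lat, semi_lon, semi_lat,
                            n_vertices = 72L) {
  stopifnot(semi_lon > 0, semi_lat > 0, n_vertices >= 8L)
  t <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  cbind(lon = center_lon + semi_lon * cos(t),
        lat = center_lat + semi_lat * sin(t))
}

#' Planar (shoelace) polygon area in squared degrees
#' @param poly Two-column vertex matrix.
#' @return Absolute area, degree^2.
#' @export
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Geodesic polygon area in km^2
#'
#' Ellipsoidal (WGS84) polygon area via [geosphere::areaPolygon()].
#' @param poly Two-column (lon, lat) vertex matrix.
#' @return Area in km^2.
#' @export
polygon_area_km2 <- function(poly) {
  geosphere::areaPolygon(poly) / 1e6
}

#' Clip a polygon to an axis-aligned rectangle (Sutherland-Hodgman)
#'
#' Clips a simple polygon against the four half-planes of the rectangle.
#' For convex subjects the result is the exact intersection; for concave
#' subjects the output ring may contain degenerate (zero-width) bridges but
#' its shoelace area still equals the true intersection area.
#'
#' @param poly Two-column vertex matrix.
#' @param xmin,xmax,ymin,ymax Rectangle bounds.
#' @return Clipped vertex matrix (possibly 0 rows).
#' @export
clip_polygon_rect <- function(poly, xmin, xmax, ymin, ymax) {
  p <- clip_halfplane(poly, 1, xmin, keep_ge = TRUE)
  p <- clip_halfplane(p, 1, xmax, keep_ge = FALSE)
  p <- clip_halfplane(p, 2, ymin, keep_ge = TRUE)
  clip_halfplane(p, 2, ymax, keep_ge = FALSE)
}

# Clip against coordinate-aligned half-plane: keep axis >= bound (keep_ge)
# or axis <= bound.
clip_halfplane <- function(poly, axis, bound, keep_ge) {
  n <- nrow(poly)
  if (is.null(n) || n == 0L) return(poly[0, , drop = FALSE])
  v <- poly[, axis]
  inside <- if (keep_ge) v >= bound else v <= bound
  out_x <- numeric(2L * n); out_y <- numeric(2L * n); k <- 0L
  other <- if (axis == 1L) 2L else 1L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (inside[i]) {
      k <- k + 1L; out_x[k] <- poly[i, axis]; out_y[k] <- poly[i, other]
    }
    if (xor(inside[i], inside[j])) {
      t <- (bound - poly[i, axis]) / (poly[j, axis] - poly[i, axis])
      k <- k + 1L
      out_x[k] <- bound
      out_y[k] <- poly[i, other] + t * (poly[j, other] - poly[i, other])
    }
  }
  if (k == 0L) return(poly[0, , drop = FALSE])
  out <- if (axis == 1L) cbind(out_x[1:k], out_y[1:k]) else
    cbind(out_y[1:k], out_x[1:k])
  colnames(out) <- c("lon", "lat")
  out
}

#' Area of intersection of a polygon with a rectangle
#' @inheritParams clip_polygon_rect
#' @return Intersection area (degree^2), 0 if disjoint.
#' @export
rect_intersection_area <- function(poly, xmin, xmax, ymin, ymax) {
  p <- clip_polygon_rect(poly, xmin, xmax, ymin, ymax)
  if (nrow(p) < 3L) return(0)
  polygon_area(p)
}

#' Test whether a polygon ring is convex
#' @param poly Two-column vertex matrix.
#' @return Logical.
#' @export
is_convex_polygon <- function(poly) {
  n <- nrow(poly)
  if (n < 4L) return(TRUE)
  x <- poly[, 1]; y <- poly[, 2]
  nxt <- c(2:n, 1L); nxt2 <- c(3:n, 1L, 2L)
  cross <- (x[nxt] - x) * (y[nxt2] - y[nxt]) - (y[nxt] - y) * (x[nxt2] - x[nxt])
  cross <- cross[abs(cross) > 1e-12 * max(abs(cross), 1e-300)]
  length(cross) == 0L || all(cross > 0) || all(cross < 0)
}

#' Polygon centroid (planar)
#' @param poly Two-column vertex matrix.
#' @return Length-2 numeric (lon, lat).
#' @export
polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  cr <- x[j] * y - x * y[j]
  a <- sum(cr) / 2
  # near-degenerate rings: the area-weighted formula cancels catastrophically
  if (abs(a) < 1e-10) return(c(mean(x), mean(y)))
  c(sum((x[j] + x) * cr) / (6 * a), sum((y[j] + y) * cr) / (6 * a))
}

#' Point-in-polygon test (even-odd rule)
#' @param lon,lat Point coordinates (vectors).
#' @param poly Two-column vertex matrix.
#' @return Logical vector.
#' @export
point_in_polygon <- function(lon, lat, poly) {
  px <- poly[, 1]; py <- poly[, 2]
  n <- length(px)
  j <- c(n, seq_len(n - 1L))
  vapply(seq_along(lon), function(k) {
    x <- lon[k]; y <- lat[k]
    crosses <- ((py > y) != (py[j] > y)) &
      (x < (px[j] - px) * (y - py) / (py[j] - py) + px)
    sum(crosses) %% 2L == 1L
  }, logical(1))
}
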