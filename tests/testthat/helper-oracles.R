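# Shared fixtures and independent brute-force oracles used across tests.

# A small global grid (coarse resolution keeps global-extent semantics).
small_grid <- function(resolution = 10) grid_spec(resolution)

random_layer <- function(grid, seed, kind = "noise") {
  v <- with_seed(seed, stats::rnorm(grid$n_cells))
  stressor_layer(paste0("rl", seed), v, kind, grid)
}

# Brute-force point binning: scan every grid cell's rectangle.
oracle_bin_points <- function(lon, lat, grid) {
  b <- cell_bounds(seq_len(grid$n_cells), grid)
  vapply(seq_along(lon), function(i) {
    hit <- which(lon[i] >= b$lon0 & lon[i] < b$lon1 &
                   lat[i] > b$lat0 & lat[i] <= b$lat1)
    stopifnot(length(hit) == 1L)
    hit
  }, integer(1))
}

# Brute-force zonal statistics from raw vectors.
oracle_zonal <- function(values, cells) {
  v <- values[cells]
  v <- v[!is.na(v)]
  if (!length(v)) return(list(min = NA_real_, max = NA_real_,
                              mean = NA_real_, median = NA_real_))
  s <- sort(v); n <- length(s)
  med <- if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  list(min = s[1], max = s[n], mean = sum(s) / n, median = med)
}

# Brute-force AUC by pair enumeration.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == "threatened" | labels == 1 | labels == TRUE]
  neg <- scores[!(labels == "threatened" | labels == 1 | labels == TRUE)]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Brute-force average precision over every distinct cut-point.
oracle_auc_pr <- function(scores, labels) {
  y <- as.integer(labels == "threatened" | labels == 1 | labels == TRUE)
  np <- sum(y)
  if (np == 0) return(NA_real_)
  ap <- 0; prev_rec <- 0
  for (t in sort(unique(scores), decreasing = TRUE)) {
    pred <- scores >= t
    tp <- sum(pred & y == 1)
    prec <- tp / sum(pred)
    rec <- tp / np
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

# Random convex range polygon (ellipse) plus its species wrapper.
random_ellipse <- function(seed, grid) {
  with_seed(seed, {
    res <- grid$resolution
    a <- stats::runif(1, 0.3, 6) * res
    b <- stats::runif(1, 0.3, 6) * res
    cx <- stats::runif(1, -150, 150)
    cy <- stats::runif(1, -60, 60)
    ellipse_polygon(cx, cy, a, b, n_vertices = 48L)
  })
}

native_poly <- function(coords, seasonal = "resident") {
  list(coords = coords, seasonal = seasonal, presence = "extant",
       origin = "native")
}

# A tiny labelled feature table with planted signal, for model-layer tests.
toy_table <- function(n = 200, seed = 1, p_noise = 4, beta = 2.5) {
  with_seed(seed, {
    x <- matrix(stats::rnorm(n * (1 + p_noise)), n)
    colnames(x) <- c("signal", paste0("noise", seq_len(p_noise)))
    pr <- stats::plogis(-0.3 + beta * x[, "signal"])
    lab <- ifelse(stats::runif(n) < pr, "threatened", "not_threatened")
    df <- data.frame(species_id = sprintf("t%04d", seq_len(n)), x,
                     label = lab, stringsAsFactors = FALSE)
    df$dom_marine <- 0L
    df
  })
}

# Small synthetic world reused by several test files (cached per session).
shared_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- world_params(n_species = 250L, n_noise = 6L, n_count = 1L,
                        resolution = 2)
      cache <<- generate_world(p, seed = 42L)
    }
    cache
  }
})

shared_features <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      w <- shared_world()
      cache <<- suppressMessages(assemble_feature_table(
        w$species, w$occurrences, w$layers, w$grid,
        ranges = w$ranges, range_cells = w$range_cells))
    }
    cache
  }
})
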