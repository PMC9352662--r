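# Seeded synthetic world: stressor layers, species with range polygons,
# occurrence points, taxonomy and Red List categories drawn from a known
# logistic threat-generating process.

#' Default world-generation parameters
#'
#' The defaults define the study conditions for the whole pipeline:
#' 2000 species on the global 0.5-degree grid, 3 causal and 20 noise
#' stressor layers plus 2 count-like layers, a strong standardized logistic
#' signal (|beta| >= 1), a DD fraction of 0.2 (about one in five assessed
#' species with range maps is Data Deficient) biased toward small ranges,
#' and small EX/EW and outdated-assessment fractions to exercise the
#' exclusion rules.
#'
#' @param ... Named overrides of any default.
#' @return Named list of parameters.
#' @export
world_params <- function(...) {
  p <- list(
    n_species = 2000L,
    n_causal = 3L,
    n_noise = 20L,
    n_count = 2L,
    resolution = 0.5,
    smooth_sd = 3,              # cells; Gaussian kernel, truncated at 3 sd
    layer_na_fraction = 0.02,   # sprinkled on noise layers
    true_intercept = -1.0,
    true_beta = c(1.5, -1.0, 1.0),  # on z-scored causal range means
    marine_beta = NULL,         # optional separate betas for marine species
    dd_fraction = 0.2,
    dd_small_range_bias = 1.0,  # weight exp(-bias * z(log range cells))
    ex_fraction = 0.01,
    outdated_fraction = 0.05,
    range_cells_min = 2,
    range_cells_max = 2000,
    lat_center_max = 65,
    p_marine = 0.3,
    multi_polygon_fraction = 0.10,  # breeding + non-breeding pairs
    nonnative_polygon_fraction = 0.05,
    occ_mu = 25, occ_size = 1,      # negative-binomial point counts
    occ_zero_fraction = 0.08,
    occ_years = 2010:2020,
    n_country_lon = 24L, n_country_lat = 12L,
    n_kingdoms = 2L, n_phyla = 4L, n_classes = 8L, n_families = 40L)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(p))
  if (length(unknown)) {
    stop(sprintf("unknown world parameter(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  p[names(ov)] <- ov
  p
}

#' Generate stressor layers
#'
#' Causal layers are spatially autocorrelated: seeded white noise smoothed
#' with a separable Gaussian kernel (`smooth_sd` cells, truncated at 3 sd,
#' periodic boundaries) and re-standardized to unit variance. Noise layers
#' are pure white noise; count-like layers are sparse Poisson counts.
#' Identical seeds give bit-identical layers.
#'
#' @param grid A [grid_spec()].
#' @param n_causal,n_noise,n_count Layer counts (`n_causal >= 1`).
#' @param seed Integer seed.
#' @param smooth_sd Gaussian kernel sd in cells.
#' @param na_fraction Fraction of cells set missing in noise layers.
#' @return List of [stressor_layer()]s named `causal_*`, `noise_*`,
#'   `count_*`.
#' @export
generate_stressor_layers <- function(grid, n_causal, n_noise, seed,
                                     n_count = 0L, smooth_sd = 3,
                                     na_fraction = 0) {
  assert_grid(grid)
  stopifnot(n_causal >= 1L, n_noise >= 0L, n_count >= 0L)
  layers <- list()
  with_seed(stage_seed(seed, "layers"), {
    for (i in seq_len(n_causal)) {
      z <- matrix(stats::rnorm(grid$n_cells), grid$n_rows, grid$n_cols)
      s <- gaussian_smooth(z, smooth_sd)
      s <- (s - mean(s)) / stats::sd(as.vector(s))
      layers[[paste0("causal_", i)]] <-
        stressor_layer(paste0("causal_", i), as_grid_vector(s, grid),
                       "autocorrelated", grid)
    }
    for (i in seq_len(n_noise)) {
      v <- stats::rnorm(grid$n_cells)
      if (na_fraction > 0) {
        v[sample.int(grid$n_cells, round(na_fraction * grid$n_cells))] <- NA
      }
      layers[[paste0("noise_", i)]] <-
        stressor_layer(paste0("noise_", i), v, "noise", grid)
    }
    for (i in seq_len(n_count)) {
      v <- stats::rpois(grid$n_cells, lambda = 0.2)
      layers[[paste0("count_", i)]] <-
        stressor_layer(paste0("count_", i), v, "count-like", grid)
    }
  })
  layers
}

# Separable Gaussian smoothing with periodic boundaries.
gaussian_smooth <- function(m, sd_cells) {
  half <- max(1L, ceiling(3 * sd_cells))
  k <- stats::dnorm(-half:half, sd = sd_cells)
  k <- k / sum(k)
  sm_cols <- function(x) {
    apply(x, 2, function(col) {
      n <- length(col)
      ext <- c(utils::tail(col, half), col, utils::head(col, half))
      as.numeric(stats::filter(ext, k, sides = 2))[(half + 1):(half + n)]
    })
  }
  t(sm_cols(t(sm_cols(m))))
}

#' Seeded rectangular "country" partition of the grid
#'
#' A fixed set of random longitude/latitude breakpoints tiles the world
#' into blocks standing in for countries; a species' native-country count
#' is the number of blocks its range cells touch.
#'
#' @param grid A [grid_spec()].
#' @param seed Integer seed.
#' @param n_lon,n_lat Number of blocks per axis.
#' @return Integer vector (length `n_cells`) of block ids.
#' @export
country_blocks <- function(grid, seed, n_lon = 24L, n_lat = 12L) {
  assert_grid(grid)
  with_seed(stage_seed(seed, "countries"), {
    lon_breaks <- sort(stats::runif(n_lon - 1L, -180, 180))
    lat_breaks <- sort(stats::runif(n_lat - 1L, -90, 90))
  })
  ctr <- cell_centers(seq_len(grid$n_cells), grid)
  lon_bin <- findInterval(ctr$lon, lon_breaks) + 1L
  lat_bin <- findInterval(ctr$lat, lat_breaks) + 1L
  as.integer((lat_bin - 1L) * n_lon + lon_bin)
}

#' Generate species, ranges, occurrences and ground-truth labels
#'
#' Ranges are axis-aligned ellipses with log-uniform cell areas, clipped to
#' world bounds. Each species' true causal features (z-scored range means
#' of the causal layers) feed the logistic threat model; the Bernoulli draw
#' gives the true threatened status, mapped to a Red List category
#' (threatened: uniform over VU/EN/CR; not: uniform over LC/NT). A
#' `dd_fraction` subset is relabelled DD with configurable bias toward
#' small ranges; a small fraction is relabelled EX/EW, and some species are
#' flagged as outdated assessments, to exercise the exclusion filters. True
#' status and probability are retained as ground truth.
#'
#' @param grid A [grid_spec()].
#' @param layers Layers from [generate_stressor_layers()].
#' @param params A [world_params()] list.
#' @param seed Integer seed.
#' @return List: `species` (data.frame incl. `true_probability`,
#'   `true_threatened`), `ranges` (named list of polygon lists),
#'   `range_cells` (named list of cell ids), `occurrences` (data.frame),
#'   `blocks` (country partition).
#' @export
generate_species <- function(grid, layers, params, seed) {
  assert_grid(grid)
  if (length(layers) == 0L) stop("empty layer list", call. = FALSE)
  p <- params
  stopifnot(p$dd_fraction >= 0, p$dd_fraction < 1)
  n <- p$n_species
  ids <- sprintf("sp%05d", seq_len(n))

  # taxonomy: families nested in classes nested in phyla nested in kingdoms
  with_seed(stage_seed(seed, "taxonomy"), {
    fam_class <- sort(sample.int(p$n_classes, p$n_families, replace = TRUE))
    cls_phylum <- sort(sample.int(p$n_phyla, p$n_classes, replace = TRUE))
    phy_kingdom <- sort(sample.int(p$n_kingdoms, p$n_phyla, replace = TRUE))
    fam_w <- stats::rexp(p$n_families) + 0.2
    fam <- sample.int(p$n_families, n, replace = TRUE, prob = fam_w)
  })
  cls <- fam_class[fam]
  phy <- cls_phylum[cls]
  kng <- phy_kingdom[phy]

  with_seed(stage_seed(seed, "domains"), {
    marine <- stats::runif(n) < p$p_marine
    terrestrial <- ifelse(marine, stats::runif(n) < 0.10,
                          stats::runif(n) < 0.90)
    freshwater <- ifelse(marine, stats::runif(n) < 0.05,
                         stats::runif(n) < 0.30)
    none <- !marine & !terrestrial & !freshwater
    terrestrial[none] <- TRUE
  })

  # range geometry
  with_seed(stage_seed(seed, "ranges"), {
    log_cells <- stats::runif(n, log(p$range_cells_min),
                              log(p$range_cells_max))
    area_deg2 <- exp(log_cells) * grid$resolution^2
    aspect <- stats::runif(n, 0.6, 1.8)
    b_ax <- sqrt(area_deg2 / (pi * aspect))
    a_ax <- aspect * b_ax
    clon <- stats::runif(n, -180, 180)
    clat <- stats::runif(n, -p$lat_center_max, p$lat_center_max)
    multi <- stats::runif(n) < p$multi_polygon_fraction
    nonnat <- stats::runif(n) < p$nonnative_polygon_fraction
    off_lon <- stats::runif(n, -2, 2) * a_ax
    off_lat <- stats::runif(n, -1, 1) * b_ax
  })
  ranges <- vector("list", n)
  names(ranges) <- ids
  for (i in seq_len(n)) {
    mk <- function(dlon, dlat, seasonal, presence = "extant",
                   origin = "native") {
      list(coords = ellipse_polygon(clon[i] + dlon, clat[i] + dlat,
                                    a_ax[i], b_ax[i]),
           seasonal = seasonal, presence = presence, origin = origin)
    }
    polys <- if (multi[i]) {
      list(mk(0, 0, "breeding"),
           mk(off_lon[i], off_lat[i], "non-breeding"))
    } else {
      list(mk(0, 0, "resident"))
    }
    if (nonnat[i]) {
      polys <- c(polys, list(mk(-off_lon[i], -off_lat[i], "resident",
                                origin = "introduced")))
    }
    ranges[[i]] <- polys
  }
  range_cells <- lapply(ranges, rasterize_range, grid = grid)

  # ground truth from z-scored causal range means
  causal <- layers[vapply(layers, `[[`, "", "kind") == "autocorrelated"]
  causal <- causal[seq_len(min(length(p$true_beta), length(causal)))]
  if (length(causal) == 0L) stop("no autocorrelated (causal) layers",
                                 call. = FALSE)
  xm <- vapply(causal, function(l) {
    vapply(range_cells, function(rc) {
      v <- l$values[rc]; mean(v[!is.na(v)])
    }, numeric(1))
  }, numeric(n))
  xz <- scale(xm)
  beta <- p$true_beta[seq_len(ncol(xz))]
  eta <- p$true_intercept + as.vector(xz %*% beta)
  if (!is.null(p$marine_beta)) {
    eta_m <- p$true_intercept + as.vector(xz %*%
                                            p$marine_beta[seq_len(ncol(xz))])
    eta[marine] <- eta_m[marine]
  }
  prob <- stats::plogis(eta)
  with_seed(stage_seed(seed, "labels"), {
    threatened <- stats::runif(n) < prob
    category <- ifelse(threatened,
                       sample(c("VU", "EN", "CR"), n, replace = TRUE),
                       sample(c("LC", "NT"), n, replace = TRUE))
    # DD relabel, biased toward small ranges
    n_dd <- round(p$dd_fraction * n)
    if (n_dd > 0L) {
      z <- as.vector(scale(log(lengths(range_cells))))
      w <- exp(-p$dd_small_range_bias * z)
      dd_idx <- sample.int(n, n_dd, prob = w)
      category[dd_idx] <- "DD"
    } else dd_idx <- integer(0)
    # EX/EW among the remaining
    pool <- setdiff(seq_len(n), dd_idx)
    n_ex <- round(p$ex_fraction * n)
    ex_idx <- if (n_ex > 0L) sample(pool, min(n_ex, length(pool))) else
      integer(0)
    category[ex_idx] <- sample(c("EX", "EW"), length(ex_idx),
                               replace = TRUE)
    outdated <- stats::runif(n) < p$outdated_fraction
    outdated[ex_idx] <- TRUE
    # habitat covariates (non-causal)
    n_hab <- 1L + stats::rpois(n, 2)
    n_sub <- n_hab + stats::rpois(n, 3)
    n_maj <- stats::rbinom(n, n_hab, 0.5)
  })

  blocks <- country_blocks(grid, seed, p$n_country_lon, p$n_country_lat)
  n_countries <- vapply(range_cells, function(rc)
    length(unique(blocks[rc])), integer(1))

  # occurrence points
  with_seed(stage_seed(seed, "occurrences"), {
    n_pts <- stats::rnbinom(n, size = p$occ_size, mu = p$occ_mu)
    n_pts[stats::runif(n) < p$occ_zero_fraction] <- 0L
    occ <- vector("list", n)
    for (i in seq_len(n)) {
      if (n_pts[i] == 0L) next
      rc <- range_cells[[i]]
      pick <- rc[sample.int(length(rc), n_pts[i], replace = TRUE)]
      b <- cell_bounds(pick, grid)
      lon <- b$lon0 + stats::runif(n_pts[i]) * grid$resolution
      lat <- b$lat1 - stats::runif(n_pts[i]) * grid$resolution
      lat <- pmin(pmax(lat, b$lat0 + 1e-9), b$lat1)
      occ[[i]] <- data.frame(species_id = ids[i], lon = lon, lat = lat,
                             year = sample(p$occ_years, n_pts[i],
                                           replace = TRUE))
    }
  })
  occurrences <- if (any(n_pts > 0L)) do.call(rbind, occ[n_pts > 0L]) else
    data.frame(species_id = character(0), lon = numeric(0),
               lat = numeric(0), year = integer(0))
  rownames(occurrences) <- NULL

  species <- data.frame(
    species_id = ids,
    kingdom = sprintf("K%02d", kng), phylum = sprintf("P%02d", phy),
    class = sprintf("C%02d", cls), family = sprintf("F%02d", fam),
    category = category,
    terrestrial = terrestrial, freshwater = freshwater, marine = marine,
    n_habitats = n_hab, n_subhabitats = n_sub, n_major_habitats = n_maj,
    n_native_countries = n_countries,
    outdated_assessment = outdated,
    true_probability = prob,
    true_threatened = threatened,
    stringsAsFactors = FALSE)
  list(species = species, ranges = ranges, range_cells = range_cells,
       occurrences = occurrences, blocks = blocks)
}

#' Generate a complete synthetic world
#'
#' @param params A [world_params()] list.
#' @param seed Integer seed; the single source of randomness (fanned out to
#'   per-stage substreams).
#' @return List of class `pe_world`: `grid`, `layers`, `species`, `ranges`,
#'   `range_cells`, `occurrences`, `blocks`, `params`, `seed`.
#' @export
generate_world <- function(params = world_params(), seed = 1L) {
  grid <- grid_spec(params$resolution)
  layers <- generate_stressor_layers(
    grid, params$n_causal, params$n_noise, seed,
    n_count = params$n_count, smooth_sd = params$smooth_sd,
    na_fraction = params$layer_na_fraction)
  sp <- generate_species(grid, layers, params, seed)
  structure(c(list(grid = grid, layers = layers), sp,
              list(params = params, seed = as.integer(seed))),
            class = "pe_world")
}

#' @export
print.pe_world <- function(x, ...) {
  cat(sprintf(
    "<pe_world> %d species, %d layers, grid %g deg, seed %d\n",
    nrow(x$species), length(x$layers), x$grid$resolution, x$seed))
  print(table(x$species$category))
  invisible(x)
}
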