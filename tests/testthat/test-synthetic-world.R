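test_that("layer generation is seeded and kinds have the right texture", {
  g <- small_grid(2)
  l1 <- generate_stressor_layers(g, 2, 3, seed = 1, n_count = 1,
                                 na_fraction = 0.02)
  l2 <- generate_stressor_layers(g, 2, 3, seed = 1, n_count = 1,
                                 na_fraction = 0.02)
  expect_identical(l1, l2)                    # bit-identical under a seed
  l3 <- generate_stressor_layers(g, 2, 3, seed = 2, n_count = 1)
  expect_false(identical(l1[[1]]$values, l3[[1]]$values))
  # spatial texture: smoothed fields autocorrelate, white noise does not
  expect_gt(moran_lag1(l1$causal_1, g), 0.3)
  expect_lt(abs(moran_lag1(l1$noise_1, g)), 0.05)
  expect_true(all(l1$count_1$values >= 0))
  expect_error(generate_stressor_layers(g, 0, 3, 1), "n_causal")
})

test_that("species generation is reproducible and respects dd_fraction", {
  p <- world_params(n_species = 150L, n_noise = 4L, n_count = 1L,
                    resolution = 4)
  w1 <- generate_world(p, seed = 5)
  w2 <- generate_world(p, seed = 5)
  expect_identical(w1$species, w2$species)
  expect_identical(w1$ranges, w2$ranges)
  expect_identical(w1$occurrences, w2$occurrences)
  # DD fraction exact up to rounding
  expect_equal(sum(w1$species$category == "DD"),
               round(p$dd_fraction * p$n_species))
  # dd_fraction = 0 -> no DD records
  p0 <- world_params(n_species = 80L, n_noise = 3L, n_count = 0L,
                     resolution = 4, dd_fraction = 0)
  w0 <- generate_world(p0, seed = 3)
  expect_equal(sum(w0$species$category == "DD"), 0)
  # EX/EW present and flagged outdated to exercise the filters
  expect_gt(sum(w1$species$category %in% c("EX", "EW")), 0)
  expect_true(all(w1$species$outdated_assessment[
    w1$species$category %in% c("EX", "EW")]))
  expect_error(generate_species(w1$grid, list(), p, 1), "empty layer")
})

test_that("DD relabelling is biased toward small-ranged species", {
  p <- world_params(n_species = 600L, n_noise = 3L, n_count = 0L,
                    resolution = 2, dd_small_range_bias = 1.5)
  w <- generate_world(p, seed = 21)
  sz <- lengths(w$range_cells)
  dd <- w$species$category == "DD"
  expect_lt(median(sz[dd]), median(sz[!dd]))
})

test_that("realized threat rate matches the generating model", {
  p <- world_params(n_species = 2000L, n_noise = 3L, n_count = 0L,
                    resolution = 2)
  w <- generate_world(p, seed = 13)
  pr <- w$species$true_probability
  se <- sqrt(sum(pr * (1 - pr))) / length(pr)
  expect_lt(abs(mean(w$species$true_threatened) - mean(pr)), 3 * se)
  # categories map from the binary truth
  expect_true(all(w$species$category[w$species$true_threatened &
                                       !(w$species$category %in%
                                           c("DD", "EX", "EW"))] %in%
                    c("VU", "EN", "CR")))
  expect_true(all(w$species$category[!w$species$true_threatened &
                                       !(w$species$category %in%
                                           c("DD", "EX", "EW"))] %in%
                    c("LC", "NT")))
})

test_that("logistic fits on true zonal features recover coefficient signs", {
  p <- world_params(n_species = 600L, n_noise = 3L, n_count = 0L,
                    resolution = 2, dd_fraction = 0, ex_fraction = 0)
  ok <- vapply(1:20, function(s) {
    w <- generate_world(p, seed = 7000 + s)
    X <- vapply(w$layers[1:3], function(l)
      vapply(w$range_cells, function(rc) mean(l$values[rc], na.rm = TRUE),
             numeric(1)), numeric(p$n_species))
    fit <- stats::glm(w$species$true_threatened ~ scale(X),
                      family = stats::binomial())
    all(sign(stats::coef(fit)[-1]) == sign(p$true_beta))
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("occurrence points fall inside world bounds and range cells", {
  w <- shared_world()
  occ <- w$occurrences
  expect_true(all(occ$lon >= -180 & occ$lon < 180))
  expect_true(all(occ$lat > -90 & occ$lat <= 90))
  expect_true(all(occ$year %in% w$params$occ_years))
  ids <- sample(unique(occ$species_id), 20)
  for (id in ids) {
    pts <- occ[occ$species_id == id, ]
    cells <- cell_of(pts$lon, pts$lat, w$grid)
    expect_true(all(cells %in% w$range_cells[[id]]))
  }
})

test_that("country counts come from the fixed block partition", {
  w <- shared_world()
  blocks <- w$blocks
  for (id in sample(w$species$species_id, 15)) {
    expect_equal(
      w$species$n_native_countries[w$species$species_id == id],
      length(unique(blocks[w$range_cells[[id]]])))
  }
})

test_that("world round-trips through disk at raster precision", {
  p <- world_params(n_species = 60L, n_noise = 3L, n_count = 1L,
                    resolution = 4)
  w <- generate_world(p, seed = 11)
  td <- withr::local_tempdir()
  write_world(w, td)
  man <- jsonlite::fromJSON(file.path(td, "world_manifest.json"))
  expect_equal(man$seed, 11)                         # seed recorded
  expect_equal(man$n_geojson_features,
               sum(lengths(w$ranges)))               # one feature per polygon
  w2 <- read_world(td)
  expect_equal(length(w2$layers), length(w$layers))
  for (nm in names(w$layers)) {
    expect_equal(w2$layers[[nm]]$values, w$layers[[nm]]$values,
                 tolerance = 1e-6)
    expect_equal(w2$layers[[nm]]$kind, w$layers[[nm]]$kind)
  }
  expect_equal(w2$species$category, w$species$category)
  expect_equal(w2$range_cells, w$range_cells,
               ignore_attr = TRUE)
  expect_equal(nrow(w2$occurrences), nrow(w$occurrences))
  # geometry survives within float precision
  expect_equal(w2$ranges[[1]][[1]]$coords, w$ranges[[1]][[1]]$coords,
               tolerance = 1e-8)
})
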