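test_that("rasterize_range handles exact-cell and tiny polygons", {
  g <- grid_spec(0.5)
  # polygon exactly covering one cell rectangle -> that cell only
  b <- cell_bounds(cell_of(10.25, 40.25, g), g)
  sq <- cbind(c(b$lon0, b$lon1, b$lon1, b$lon0),
              c(b$lat0, b$lat0, b$lat1, b$lat1))
  expect_identical(rasterize_range(list(native_poly(sq)), g), b$cell)
  # tiny polygon strictly inside one cell -> that cell via intersection rule
  tiny <- ellipse_polygon(10.3, 40.3, 0.01, 0.01)
  expect_identical(rasterize_range(list(native_poly(tiny)), g), b$cell)
})

test_that("rasterize_range never returns empty and filters non-native", {
  g <- grid_spec(0.5)
  degenerate <- ellipse_polygon(7.25, 7.25, 1e-9, 1e-9)
  cells <- rasterize_range(list(native_poly(degenerate)), g)
  expect_length(cells, 1L)
  expect_identical(cells, cell_of(7.25, 7.25, g))
  intro <- list(coords = ellipse_polygon(0, 0, 2, 2),
                seasonal = "resident", presence = "extant",
                origin = "introduced")
  expect_error(rasterize_range(list(intro), g), "native")
})

test_that("band rasterization matches exhaustive per-cell clipping", {
  g <- small_grid(5)
  for (s in 1:25) {
    poly <- random_ellipse(s, g)
    fast <- rasterize_range(list(native_poly(poly)), g, method = "bands")
    slow <- rasterize_range(list(native_poly(poly)), g,
                            method = "exhaustive")
    expect_identical(fast, slow)
  }
})

test_that("seasonal polygons union before extraction", {
  g <- grid_spec(1)
  p1 <- native_poly(ellipse_polygon(10, 10, 2, 2), "breeding")
  p2 <- native_poly(ellipse_polygon(30, -5, 3, 1), "non-breeding")
  cells <- rasterize_range(list(p1, p2), g)
  expect_identical(cells,
                   sort(union(rasterize_range(list(p1), g),
                              rasterize_range(list(p2), g))))
})

test_that("occurrence binning counts points and collapses duplicate cells", {
  g <- grid_spec(0.5)
  pts <- data.frame(lon = c(0.1, 0.2), lat = c(0.1, 0.3))
  oc <- occurrence_cells(pts, g)
  expect_equal(oc$n_points, 2L)
  expect_length(oc$cells, 1L)
  # half-open convention at an interior edge
  oc2 <- occurrence_cells(data.frame(lon = 0.5, lat = 0.2), g)
  expect_equal(cell_bounds(oc2$cells, g)$lon0, 0.5)
  # 1000 random points against brute-force binning
  gg <- small_grid(12)
  with_seed(3, {
    lon <- stats::runif(1000, -180, 179.99)
    lat <- stats::runif(1000, -89.99, 90)
  })
  oc3 <- occurrence_cells(data.frame(lon = lon, lat = lat), gg)
  expect_identical(oc3$cells,
                   sort(unique(oracle_bin_points(lon, lat, gg))))
  expect_error(occurrence_cells(data.frame(lon = 200, lat = 0), g),
               "index 1")
})

test_that("zonal statistics follow the stated conventions", {
  g <- small_grid(30)
  const <- stressor_layer("c", rep(3.5, g$n_cells), "noise", g)
  zs <- zonal_stats(const, c(1L, 5L, 9L))
  expect_equal(unlist(zs), c(min = 3.5, max = 3.5, mean = 3.5,
                             median = 3.5))
  v <- rep(NA_real_, g$n_cells)
  v[1:4] <- c(1, 2, 3, 10)
  l <- stressor_layer("l", v, "noise", g)
  zs2 <- zonal_stats(l, 1:4)
  expect_equal(unlist(zs2), c(min = 1, max = 10, mean = 4, median = 2.5))
  # all-missing cell set -> all four statistics missing
  expect_true(all(is.na(unlist(zonal_stats(l, 10:12)))))
  expect_error(zonal_stats(l, integer(0)), "non-empty")
})

test_that("zonal statistics match a brute-force oracle on 150 instances", {
  g <- small_grid(20)
  for (s in 1:150) {
    with_seed(s + 1000, {
      v <- stats::rnorm(g$n_cells)
      v[sample.int(g$n_cells, g$n_cells * 0.2)] <- NA
      cells <- sample.int(g$n_cells, sample(1:40, 1))
    })
    got <- zonal_stats(v, cells)
    want <- oracle_zonal(v, cells)
    expect_equal(got, want, tolerance = 1e-12)
    if (!is.na(got$min)) {
      expect_true(got$min <= got$mean && got$mean <= got$max)
      expect_true(got$min <= got$median && got$median <= got$max)
    }
  }
})

test_that("count-layer sums over ranges match brute force", {
  g <- small_grid(20)
  with_seed(9, {
    v <- stats::rpois(g$n_cells, 0.5)
    cells <- sample.int(g$n_cells, 25)
  })
  l <- stressor_layer("dams", v, "count-like", g)
  expect_equal(count_points_in_range(l, cells), sum(v[cells]))
  z <- stressor_layer("z", rep(0, g$n_cells), "count-like", g)
  expect_equal(count_points_in_range(z, cells), 0L)
  one <- rep(0, g$n_cells); one[cells[1]] <- 7
  l7 <- stressor_layer("pp", one, "count-like", g)
  expect_equal(count_points_in_range(l7, cells), 7L)
  expect_error(count_points_in_range(random_layer(g, 1), cells),
               "count-like")
})

test_that("feature table has the documented shape and missingness", {
  w <- shared_world()
  ft <- shared_features()
  n_zonal_layers <- sum(vapply(w$layers, `[[`, "", "kind") != "count-like")
  zonal_cols <- grep("_(range|occ)_(min|max|mean|median)$", names(ft))
  expect_length(zonal_cols, n_zonal_layers * 4 * 2)
  expect_false(any(duplicated(ft$species_id)))
  # EX/EW dropped, DD rows have NA label
  expect_setequal(unique(ft$label[!is.na(ft$label)]),
                  c("threatened", "not_threatened"))
  dd_ids <- w$species$species_id[w$species$category == "DD"]
  expect_true(all(is.na(ft$label[ft$species_id %in% dd_ids])))
  # no-occurrence species: zero points but missing derived columns
  no_occ <- ft$n_occurrence_points == 0
  expect_true(any(no_occ))
  expect_true(all(is.na(ft$n_occurrence_cells[no_occ])))
  expect_true(all(is.na(ft[no_occ, grep("_occ_mean$", names(ft))[1]])))
  # column manifest covers every zonal column
  man <- attr(ft, "column_manifest")
  expect_true(all(!is.na(man$statistic[match(names(ft)[zonal_cols],
                                             man$name)])))
})

test_that("feature extraction is invariant to species input order", {
  w <- shared_world()
  ft <- shared_features()
  with_seed(8, perm <- sample(nrow(w$species)))
  ft2 <- suppressMessages(assemble_feature_table(
    w$species[perm, ], w$occurrences, w$layers, w$grid,
    ranges = w$ranges, range_cells = w$range_cells))
  expect_equal(as.data.frame(ft), as.data.frame(ft2))
})

test_that("feature table CSV rewrite is byte-identical", {
  ft <- shared_features()
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  data.table::fwrite(as.data.frame(ft), f1)
  data.table::fwrite(as.data.frame(ft), f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("random-value imputation draws from training pools only", {
  ft <- shared_features()
  # no missing values -> unchanged
  clean <- ft[, c("species_id", "range_cells", "range_km2", "label")]
  expect_identical(impute_missing(clean, 1)[names(clean)], clean)
  # imputed entries come from the observed training values of their column
  train_ids <- ft$species_id[seq(1, nrow(ft), by = 2)]
  imp <- make_imputer(ft, train_ids)
  out <- apply_imputer(imp, ft, seed = 4)
  col <- grep("_occ_mean$", names(ft), value = TRUE)[1]
  was_na <- is.na(ft[[col]])
  pool <- ft[[col]][ft$species_id %in% train_ids & !was_na]
  expect_true(all(out[[col]][was_na] %in% pool))
  expect_identical(out[[col]][!was_na], ft[[col]][!was_na])
  # determinism
  out2 <- apply_imputer(imp, ft, seed = 4)
  expect_identical(out, out2)
  # all-missing column dropped with a warning
  ft$ghost <- NA_real_
  expect_warning(res <- impute_missing(ft, 1), "ghost")
  expect_false("ghost" %in% names(res))
})
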