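make_pred <- function(ids, pe, thr = 0.5) {
  data.frame(species_id = ids, pe_score = pe,
             predicted_label = ifelse(pe >= thr, "threatened",
                                      "not_threatened"))
}

test_that("fraction map follows the counting rule and masking", {
  g <- small_grid(30)
  rc <- list(a = c(1L, 2L), b = c(1L, 3L), c = c(1L, 2L))
  pred <- make_pred(c("a", "b", "c"), c(0.9, 0.8, 0.1))
  fr <- fraction_dd_threatened(pred, rc, g)
  expect_equal(fr$frac[1], 2 / 3)      # 3 DD present, 2 threatened
  expect_equal(fr$frac[2], 1 / 2)
  expect_equal(fr$frac[3], 1)
  expect_true(is.na(fr$frac[4]))       # no DD -> masked, not zero
  expect_error(fraction_dd_threatened(make_pred("zz", 0.5), rc, g),
               "without range")
})

test_that("percent change map implements the stated formula", {
  g <- small_grid(30)
  rc <- list(ds1 = 1L, ds2 = 1L, dd1 = 1L, dd2 = 2L)
  ds <- make_pred(c("ds1", "ds2"), c(0.2, 0.3))
  dd <- make_pred(c("dd1", "dd2"), c(0.55, 0.9))
  pc <- percent_change_map(ds, dd, rc, g)
  # DS mean 0.25, pooled mean (0.2+0.3+0.55)/3 = 0.35 -> +40%
  expect_equal(pc$mean_pe_ds[1], 0.25)
  expect_equal(pc$mean_pe_all[1], 0.35)
  expect_equal(pc$pct_change[1], 40)
  # DS mean 0.25 vs combined 0.30 -> +20%
  dd2 <- make_pred("dd1", 0.4)
  pc2 <- percent_change_map(ds, dd2, list(ds1 = 1L, ds2 = 1L, dd1 = 1L), g)
  expect_equal(pc2$pct_change[1], 20)
  # DD mean equal to DS mean -> 0%
  pc3 <- percent_change_map(ds, make_pred("dd1", 0.25),
                            list(ds1 = 1L, ds2 = 1L, dd1 = 1L), g)
  expect_equal(pc3$pct_change[1], 0)
  # no DS -> masked
  expect_true(is.na(pc$pct_change[2]))
  expect_equal(pc$mean_pe_all[2], 0.9)
})

test_that("aggregation grids match brute-force per-cell recounts", {
  w <- shared_world()
  ft <- shared_features()
  with_seed(19, pe <- stats::runif(nrow(ft)))
  pred <- make_pred(ft$species_id, pe, thr = 0.45)
  dd_ids <- ft$species_id[is.na(ft$label)]
  ds_ids <- setdiff(ft$species_id, dd_ids)
  pred_dd <- pred[pred$species_id %in% dd_ids, ]
  pred_ds <- pred[pred$species_id %in% ds_ids, ]
  rc <- attr(ft, "range_cells")
  fr <- fraction_dd_threatened(pred_dd, rc, w$grid)
  pc <- percent_change_map(pred_ds, pred_dd, rc, w$grid)
  # brute force over a random sample of cells
  with_seed(29, cells <- sample.int(w$grid$n_cells, 400))
  for (cell in cells) {
    dd_here <- dd_ids[vapply(dd_ids, function(i) cell %in% rc[[i]],
                             logical(1))]
    ds_here <- ds_ids[vapply(ds_ids, function(i) cell %in% rc[[i]],
                             logical(1))]
    thr_here <- sum(pred_dd$predicted_label[match(dd_here,
                                                  pred_dd$species_id)] ==
                      "threatened")
    if (length(dd_here) == 0) {
      expect_true(is.na(fr$frac[cell]))
    } else {
      expect_equal(fr$frac[cell], thr_here / length(dd_here))
    }
    if (length(ds_here) == 0) {
      expect_true(is.na(pc$pct_change[cell]))
    } else {
      m_ds <- mean(pred_ds$pe_score[match(ds_here, pred_ds$species_id)])
      m_all <- mean(pred$pe_score[match(c(ds_here, dd_here),
                                        pred$species_id)])
      expect_equal(pc$mean_pe_ds[cell], m_ds, tolerance = 1e-10)
      expect_equal(pc$mean_pe_all[cell], m_all, tolerance = 1e-10)
      if (m_ds > 0) {
        expect_equal(pc$pct_change[cell], 100 * (m_all - m_ds) / m_ds,
                     tolerance = 1e-10)
      }
    }
  }
  # range invariants and the conservation identity
  expect_true(all(fr$frac[!is.na(fr$frac)] >= 0 &
                    fr$frac[!is.na(fr$frac)] <= 1))
  expect_true(all(pc$mean_pe_all[!is.na(pc$mean_pe_all)] >= 0 &
                    pc$mean_pe_all[!is.na(pc$mean_pe_all)] <= 1))
  ok <- !is.na(fr$frac)
  expect_equal(sum(fr$frac[ok] * fr$n_dd[ok]) / sum(fr$n_dd[ok]),
               sum(fr$n_dd_threatened) / sum(fr$n_dd))
  # bit-exact reproducibility from the same inputs
  expect_identical(fr, fraction_dd_threatened(pred_dd, rc, w$grid))
})

test_that("per-class summary matches a group-by on the predictions", {
  w <- shared_world()
  ft <- shared_features()
  dd_ids <- ft$species_id[is.na(ft$label)]
  with_seed(31, pe <- stats::runif(length(dd_ids)))
  pred <- make_pred(dd_ids, pe, thr = 0.5)
  s <- per_class_summary(pred, w$species)
  expect_true(all(s$n_dd > 0))                      # 0-DD classes omitted
  sp_class <- w$species$class[match(dd_ids, w$species$species_id)]
  for (i in seq_len(nrow(s))) {
    in_cl <- sp_class == s$class[i]
    expect_equal(s$n_dd[i], sum(in_cl))
    expect_equal(s$n_dd_predicted_threatened[i],
                 sum(pred$predicted_label[in_cl] == "threatened"))
    expect_equal(s$frac_dd_threatened[i],
                 mean(pred$predicted_label[in_cl] == "threatened"))
  }
  # a class with 10 DD of which 4 threatened -> 0.4
  toy_sp <- data.frame(species_id = sprintf("q%02d", 1:12),
                       class = rep(c("CX", "CY"), c(10, 2)),
                       category = "DD")
  toy_pred <- make_pred(toy_sp$species_id[1:10],
                        c(rep(0.9, 4), rep(0.1, 6)))
  s2 <- per_class_summary(toy_pred, toy_sp)
  expect_equal(s2$frac_dd_threatened[s2$class == "CX"], 0.4)
  expect_false("CY" %in% s2$class)
})
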