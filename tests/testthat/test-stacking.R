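test_that("stratified folds are balanced and deterministic", {
  y <- rep(c("threatened", "not_threatened"), c(37, 63))
  f <- stratified_folds(y, 10, seed = 4)
  expect_true(max(table(f)) - min(table(f)) <= 1)
  for (cl in unique(y)) {
    tab <- table(f[y == cl])
    expect_true(max(tab) - min(tab) <= 1)
  }
  expect_identical(f, stratified_folds(y, 10, seed = 4))
  expect_false(identical(f, stratified_folds(y, 10, seed = 5)))
})

test_that("out-of-fold scores carry signal and respect fold discipline", {
  tab <- toy_table(n = 200, seed = 7)
  enc <- encode_features(tab)
  roster <- default_roster()[c("glm_lasso", "random_forest")]
  cv <- cv_oof(enc$x, tab$label, roster, folds = 5, seed = 2)
  expect_false(anyNA(cv$oof))
  expect_true(all(cv$oof >= 0 & cv$oof <= 1))
  for (b in colnames(cv$oof)) {
    expect_gt(auc(cv$oof[, b], tab$label), 0.5)
  }
  cv2 <- cv_oof(enc$x, tab$label, roster, folds = 5, seed = 2)
  expect_identical(cv$fold_assignment, cv2$fold_assignment)
  expect_equal(cv$oof, cv2$oof)
})

test_that("meta-learner zeroes noise learners and keeps coefficients non-negative", {
  zero_rate <- vapply(1:10, function(s) {
    with_seed(900 + s, {
      n <- 400
      p <- stats::plogis(stats::rnorm(n, sd = 2))
      y <- ifelse(stats::runif(n) < p, "threatened", "not_threatened")
      oof <- cbind(bayes = p,
                   noise1 = stats::runif(n), noise2 = stats::runif(n))
    })
    meta <- fit_meta(oof, y, seed = s)
    expect_true(all(meta$coefficients >= 0))
    all(meta$coefficients[c("noise1", "noise2")] == 0)
  }, logical(1))
  expect_gte(sum(zero_rate), 9)
})

test_that("single-learner stack is a monotone transform of that learner", {
  with_seed(41, {
    n <- 300
    sc <- stats::runif(n)
    y <- ifelse(stats::runif(n) < sc, "threatened", "not_threatened")
  })
  oof <- matrix(sc, ncol = 1, dimnames = list(NULL, "only"))
  meta <- fit_meta(oof, y, seed = 1)
  combined <- perisk:::meta_score(meta, oof)
  expect_equal(stats::cor(combined, sc, method = "spearman"), 1)
})

test_that("degenerate constant out-of-fold column warns but fits", {
  with_seed(43, {
    y <- sample(c("threatened", "not_threatened"), 100, TRUE)
    oof <- cbind(a = stats::runif(100), b = rep(0.5, 100))
  })
  expect_warning(meta <- fit_meta(oof, y, seed = 1), "degenerate")
  expect_true(all(meta$coefficients >= 0))
})

test_that("threshold choice equals the brute-force F1 optimum", {
  brute_best <- function(scores, y) {
    cand <- sort(unique(scores))
    f1 <- vapply(cand, function(t) {
      tp <- sum(scores >= t & y == 1)
      if (tp == 0) return(NA_real_)
      fp <- sum(scores >= t & y == 0)
      fn <- sum(scores < t & y == 1)
      2 * tp / (2 * tp + fp + fn)
    }, numeric(1))
    cand[which.max(f1)]   # which.max takes the first (smallest) maximiser
  }
  for (s in 1:30) {
    with_seed(s + 800, {
      sc <- round(stats::runif(40), 2)
      y <- stats::rbinom(40, 1, 0.4)
    })
    if (sum(y) == 0) next
    t_star <- choose_threshold(sc, y)
    expect_equal(t_star, min(max(brute_best(sc, y), 1e-9), 1 - 1e-9))
    expect_true(t_star > 0 && t_star < 1)
  }
  # perfectly separated scores: smallest optimal cut-point returned
  expect_equal(choose_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)),
               0.8)
})

test_that("training ignores everything outside the training rows", {
  tab <- toy_table(n = 240, seed = 70)
  tr <- tab[1:160, ]
  m1 <- suppressWarnings(train_stacked(tr, folds = 5, seed = 9,
                                       select = FALSE))
  # corrupt all non-training rows; the trained model must be unchanged
  tab2 <- tab
  tab2[161:240, c("signal", paste0("noise", 1:4))] <- 99
  m2 <- suppressWarnings(train_stacked(tab2[1:160, ], folds = 5, seed = 9,
                                       select = FALSE))
  expect_equal(m1$meta, m2$meta)
  expect_identical(m1$threshold, m2$threshold)
  expect_equal(m1$oof, m2$oof)
  p1 <- predict(m1, tab[161:240, ])
  p2 <- predict(m2, tab[161:240, ])
  expect_equal(p1, p2)
})

test_that("predictions are probabilities and DD rows never train", {
  w <- shared_world()
  ft <- shared_features()
  sp <- apply_outdated_rule(w$species[w$species$species_id %in%
                                        ft$species_id, ])
  split <- suppressMessages(stratified_split(sp, seed = 6))
  ft2 <- ft[ft$species_id %in% split$species_id, ]
  tr <- ft2[ft2$species_id %in% split$species_id[split$role == "train"], ]
  m <- suppressWarnings(train_stacked(tr, folds = 5, seed = 8,
                                      boruta_R = 10))
  dd <- ft2[ft2$species_id %in%
              split$species_id[split$role == "dd_holdout"], ]
  pred <- predict(m, dd)
  expect_true(all(pred$pe_score >= 0 & pred$pe_score <= 1))
  expect_length(intersect(dd$species_id, m$train_ids), 0)
  expect_identical(pred$predicted_label,
                   ifelse(pred$pe_score >= m$threshold, "threatened",
                          "not_threatened"))
})

test_that("partition-2 models are trained on disjoint domain subsets", {
  w <- shared_world()
  ft <- shared_features()
  sp <- apply_outdated_rule(w$species[w$species$species_id %in%
                                        ft$species_id, ])
  split <- suppressMessages(stratified_split(sp, seed = 10))
  split <- split[match(ft$species_id, split$species_id), ]
  roster <- default_roster()[c("glm_lasso", "random_forest")]
  models <- suppressWarnings(train_partitions(
    ft, split, roster = roster, seed = 12, folds = 5, boruta_R = 8))
  marine_ids <- ft$species_id[ft$dom_marine == 1L]
  if (!is.null(models$marine)) {
    expect_length(intersect(models$marine$train_ids,
                            setdiff(ft$species_id, marine_ids)), 0)
  }
  if (!is.null(models$non_marine)) {
    expect_length(intersect(models$non_marine$train_ids, marine_ids), 0)
  }
  # both partitions score the same test species
  test_tab <- ft[!is.na(split$role) & split$role == "test", ]
  p1 <- predict(models$all, test_tab)
  p2 <- predict_partition2(models, test_tab)
  expect_setequal(p1$species_id, p2$species_id)
})

test_that("partition-2 subsets below 50 training rows are skipped", {
  tab <- toy_table(n = 120, seed = 3)
  tab$dom_marine <- c(rep(1L, 10), rep(0L, 110))
  split <- data.frame(species_id = tab$species_id,
                      role = rep(c("train", "test"), c(90, 30)))
  expect_warning(
    models <- train_partitions(tab, split,
                               roster = default_roster()["glm_lasso"],
                               seed = 2, folds = 5, select = FALSE),
    "skipped")
  expect_null(models$marine)
})

test_that("partition selection averages per-class AUC with tie to all", {
  df <- data.frame(score = c(0.9, 0.8, 0.2, 0.1, 0.7, 0.6, 0.3, 0.4,
                             0.5, 0.5),
                   label = rep(c("threatened", "not_threatened"), 5),
                   class = rep(c("A", "B"), each = 5))
  # identical scores in both partitions -> tie -> "all"
  ch <- select_partition(list(all = df, partition2 = df))
  expect_equal(ch$chosen, "all")
  # classes with fewer than 5 members are excluded from the average
  df_small <- df
  df_small$class <- c(rep("A", 6), rep("Z", 4))
  ch2 <- select_partition(list(all = df_small, partition2 = df_small))
  expect_false("Z" %in% ch2$per_class$class)
  # a clearly better partition wins
  good <- df; good$score <- ifelse(good$label == "threatened", 0.9, 0.1)
  bad <- df; bad$score <- ifelse(bad$label == "threatened", 0.1, 0.9)
  ch3 <- select_partition(list(all = bad, partition2 = good))
  expect_equal(ch3$chosen, "partition2")
})

test_that("marine and non-marine worlds with opposite effects favour partition 2", {
  wins <- vapply(1:10, function(s) {
    p <- world_params(n_species = 500L, n_noise = 4L, n_count = 0L,
                      resolution = 2, dd_fraction = 0,
                      ex_fraction = 0, outdated_fraction = 0,
                      p_marine = 0.5,
                      true_beta = c(2, 1.5, 0),
                      marine_beta = c(-2, -1.5, 0))
    w <- generate_world(p, seed = 4000 + s)
    ft <- suppressMessages(assemble_feature_table(
      w$species, w$occurrences, w$layers, w$grid,
      ranges = w$ranges, range_cells = w$range_cells))
    split <- suppressMessages(stratified_split(w$species, seed = s))
    split <- split[match(ft$species_id, split$species_id), ]
    roster <- default_roster()["glm_lasso"]
    models <- suppressWarnings(train_partitions(
      ft, split, roster = roster, seed = s, folds = 5, select = FALSE))
    sc <- list()
    cls <- function(ids) ft$class[match(ids, ft$species_id)]
    sc$all <- data.frame(score = models$all$oof_super,
                         label = models$all$train_labels,
                         class = cls(models$all$train_ids))
    p2 <- list()
    for (part in c("marine", "non_marine")) {
      m <- models[[part]]
      if (is.null(m)) next
      p2[[part]] <- data.frame(score = m$oof_super,
                               label = m$train_labels,
                               class = cls(m$train_ids))
    }
    sc$partition2 <- do.call(rbind, p2)
    select_partition(sc)$chosen == "partition2"
  }, logical(1))
  expect_gte(sum(wins), 8)
})
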