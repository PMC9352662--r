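# Stacked super-learner: base learners fitted with stratified 10-fold CV
# (minority oversampling inside each training fold), combined by a
# non-negative L1-regularized logistic meta-learner on the out-of-fold
# prediction matrix; final base models are refit on the full training set.

POSITIVE <- "threatened"

#' Default base-learner roster
#'
#' Four learner families: an L1-regularized logistic GLM, a random forest,
#' gradient boosted classification trees and an extremely randomized
#' forest. Hyperparameters are small fixed grids chosen for desk-scale
#' determinism; deep neural networks are deliberately not included.
#'
#' @return Named list of base-learner specifications.
#' @export
default_roster <- function() {
  list(
    glm_lasso = list(kind = "regularized-GLM",
                     params = list(alpha = 1, nfolds = 5)),
    random_forest = list(kind = "random-forest",
                         params = list(num.trees = 300,
                                       min.node.size = 5)),
    gbt = list(kind = "gradient-boosted-trees",
               params = list(nrounds = 80, eta = 0.2, max_depth = 4,
                             subsample = 0.8)),
    extra_trees = list(kind = "extremely-randomized-trees",
                       params = list(num.trees = 300)))
}

fit_base <- function(spec, x, y, seed) {
  y01 <- as.integer(y == POSITIVE)
  p <- spec$params
  model <- switch(
    spec$kind,
    "regularized-GLM" = {
      foldid <- with_seed(stage_seed(seed, "glm_folds"),
                          sample(rep_len(seq_len(p$nfolds), nrow(x))))
      glmnet::cv.glmnet(x, y01, family = "binomial", alpha = p$alpha,
                        foldid = foldid)
    },
    "random-forest" = ranger::ranger(
      y = factor(y, levels = c("not_threatened", "threatened")),
      x = as.data.frame(x), probability = TRUE,
      num.trees = p$num.trees, min.node.size = p$min.node.size,
      seed = stage_seed(seed, "rf"), num.threads = 1L),
    "gradient-boosted-trees" = {
      set.seed(stage_seed(seed, "gbt"))
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = p$eta,
                      max_depth = p$max_depth, subsample = p$subsample,
                      nthread = 1L,
                      seed = stage_seed(seed, "gbt")),
        data = xgboost::xgb.DMatrix(x, label = y01),
        nrounds = p$nrounds, verbose = 0)
    },
    "extremely-randomized-trees" = ranger::ranger(
      y = factor(y, levels = c("not_threatened", "threatened")),
      x = as.data.frame(x), probability = TRUE,
      num.trees = p$num.trees, splitrule = "extratrees",
      num.random.splits = 1L, replace = FALSE, sample.fraction = 1,
      seed = stage_seed(seed, "xt"), num.threads = 1L),
    stop(sprintf("unknown base-learner kind: %s", spec$kind),
         call. = FALSE))
  list(kind = spec$kind, model = model, features = colnames(x))
}

predict_base <- function(fit, x) {
  x <- x[, fit$features, drop = FALSE]
  switch(
    fit$kind,
    "regularized-GLM" = as.numeric(
      predict(fit$model, x, s = "lambda.1se", type = "response")),
    "random-forest" = ,
    "extremely-randomized-trees" = as.numeric(
      predict(fit$model, data = as.data.frame(x),
              num.threads = 1L)$predictions[, POSITIVE]),
    "gradient-boosted-trees" = as.numeric(
      predict(fit$model, xgboost::xgb.DMatrix(x))))
}

#' Stratified fold assignment
#'
#' Shuffles within each class (seeded), concatenates the classes and deals
#' cells cyclically, so overall fold sizes and per-class fold counts each
#' differ by at most one.
#'
#' @param y Label vector.
#' @param folds Number of folds.
#' @param seed Integer seed.
#' @return Integer fold ids in `1..folds`.
#' @export
stratified_folds <- function(y, folds, seed) {
  ord <- with_seed(stage_seed(seed, "folds"), {
    unlist(lapply(split(seq_along(y), y), function(ix)
      if (length(ix) > 1L) sample(ix) else ix), use.names = FALSE)
  })
  fold <- integer(length(y))
  fold[ord] <- rep_len(seq_len(folds), length(y))
  fold
}

#' Out-of-fold base-learner prediction matrix
#'
#' Stratified k-fold CV: inside each fold's training part the minority
#' class is oversampled before fitting, and the held-out fold is scored by
#' the model that never saw it. If a fold ends up single-class the split is
#' reshuffled once with a derived seed, then errors.
#'
#' @param x Numeric feature matrix (rownames = species ids).
#' @param y Label vector (`threatened`/`not_threatened`).
#' @param roster Base-learner roster (see [default_roster()]).
#' @param folds Number of folds (default 10).
#' @param seed Integer seed.
#' @return List: `oof` (matrix rows = species, cols = learners),
#'   `fold_assignment`.
#' @export
cv_oof <- function(x, y, roster, folds = 10L, seed = 1L) {
  stopifnot(folds >= 2L, length(unique(y)) == 2L)
  fold <- stratified_folds(y, folds, seed)
  if (min(table(fold, y)) == 0L) {
    fold <- stratified_folds(y, folds, stage_seed(seed, "reshuffle"))
    if (min(table(fold, y)) == 0L) {
      stop("a fold has a single class even after reshuffling",
           call. = FALSE)
    }
  }
  oof <- matrix(NA_real_, nrow(x), length(roster),
                dimnames = list(rownames(x), names(roster)))
  for (f in seq_len(folds)) {
    tr <- which(fold != f)
    te <- which(fold == f)
    os <- oversample_indices(y[tr], stage_seed(seed, paste0("os_fold", f)))
    xtr <- x[tr[os], , drop = FALSE]
    ytr <- y[tr][os]
    for (b in names(roster)) {
      fit <- fit_base(roster[[b]], xtr, ytr,
                      stage_seed(seed, paste(b, "fold", f)))
      oof[te, b] <- predict_base(fit, x[te, , drop = FALSE])
    }
  }
  list(oof = oof, fold_assignment = fold)
}

#' Fit the non-negative L1 logistic meta-learner
#'
#' Minimizes logistic loss over the out-of-fold score matrix subject to all
#' learner coefficients being >= 0 (free intercept), with the L1 penalty
#' chosen by internal cross-validation under the 1-SE rule; exact zeros are
#' expected (sparse ensembles).
#'
#' @param oof Out-of-fold score matrix (species x learners).
#' @param y Labels.
#' @param seed Integer seed.
#' @return List: `intercept`, `coefficients` (named, all >= 0), `lambda`.
#' @export
fit_meta <- function(oof, y, seed = 1L) {
  if (anyNA(oof)) stop("out-of-fold matrix has missing entries",
                       call. = FALSE)
  y01 <- as.integer(y == POSITIVE)
  if (ncol(oof) == 1L) {
    fit <- stats::glm(y01 ~ oof[, 1], family = stats::binomial())
    co <- max(0, unname(stats::coef(fit)[2]))
    return(list(intercept = unname(stats::coef(fit)[1]),
                coefficients = stats::setNames(co, colnames(oof)),
                lambda = NA_real_))
  }
  sds <- apply(oof, 2, stats::sd)
  if (any(sds < 1e-12)) {
    warning("degenerate all-equal out-of-fold column(s): ",
            paste(colnames(oof)[sds < 1e-12], collapse = ", "),
            call. = FALSE)
  }
  foldid <- with_seed(stage_seed(seed, "meta_folds"),
                      sample(rep_len(1:5, length(y01))))
  cv <- glmnet::cv.glmnet(oof, y01, family = "binomial", alpha = 1,
                          lower.limits = 0, standardize = FALSE,
                          foldid = foldid)
  co <- as.numeric(stats::coef(cv, s = "lambda.1se"))
  list(intercept = co[1],
       coefficients = stats::setNames(pmax(co[-1], 0), colnames(oof)),
       lambda = cv$lambda.1se)
}

meta_score <- function(meta, score_matrix) {
  eta <- meta$intercept +
    as.vector(score_matrix[, names(meta$coefficients), drop = FALSE] %*%
                meta$coefficients)
  stats::plogis(eta)
}

#' Decision threshold maximizing F1 on out-of-fold scores
#'
#' Exhaustive search over all observed score cut-points (predicting
#' threatened iff score >= threshold); ties are broken toward the smallest
#' threshold.
#'
#' @param scores Out-of-fold super-learner scores in `[0, 1]`.
#' @param labels Reference labels.
#' @return The F1-optimal threshold (strictly inside `(0, 1)`).
#' @export
choose_threshold <- function(scores, labels) {
  y <- as_binary_label(labels)
  cand <- sort(unique(scores))
  best_f1 <- -1; best_t <- 0.5
  for (t in cand) {
    pred <- scores >= t
    tp <- sum(pred & y == 1L)
    fp <- sum(pred & y == 0L)
    fn <- sum(!pred & y == 1L)
    if (tp == 0L) next
    f1 <- 2 * tp / (2 * tp + fp + fn)
    if (f1 > best_f1 + 1e-12) {
      best_f1 <- f1; best_t <- t
    }
  }
  min(max(best_t, 1e-9), 1 - 1e-9)
}

#' Train a stacked super-learner on a training feature table
#'
#' Pipeline: fit the random-value imputer on the training rows, one-hot
#' encode, run shadow-feature selection, build the out-of-fold matrix with
#' [cv_oof()] (oversampling inside folds), fit the non-negative lasso
#' meta-learner, pick the F1-optimal threshold on out-of-fold super-learner
#' scores, and refit every base learner on the full (oversampled) training
#' set for prediction.
#'
#' @param train_table Feature table of training rows (labels present).
#' @param roster Base-learner roster.
#' @param folds CV folds (default 10).
#' @param seed Integer seed.
#' @param boruta_R,boruta_alpha,boruta_trees Selection parameters.
#' @param select Run feature selection (default TRUE; FALSE keeps all
#'   columns, used by small unit fixtures).
#' @param confirmed_features Optional precomputed confirmed column names
#'   (from a selection run on this same training data); skips the internal
#'   selection run.
#' @param partition_tag One of `"all"`, `"marine"`, `"non_marine"`.
#' @return Object of class `pe_stacked`.
#' @export
train_stacked <- function(train_table, roster = default_roster(),
                          folds = 10L, seed = 1L, boruta_R = 50L,
                          boruta_alpha = 0.01, boruta_trees = 64L,
                          select = TRUE, confirmed_features = NULL,
                          partition_tag = "all") {
  stopifnot(!anyNA(train_table$label))
  imputer <- make_imputer(train_table)
  tab <- apply_imputer(imputer, train_table, stage_seed(seed, "train_imp"))
  enc <- encode_features(tab)
  selection <- NULL
  if (!is.null(confirmed_features)) {
    features <- intersect(confirmed_features, colnames(enc$x))
    if (length(features) < 2L) {
      warning("fewer than 2 confirmed features; keeping all columns",
              call. = FALSE)
      features <- colnames(enc$x)
    }
  } else if (select) {
    selection <- boruta_select(enc$x, tab$label, R = boruta_R,
                               alpha = boruta_alpha,
                               seed = stage_seed(seed, "boruta"),
                               blocks = enc$blocks,
                               num_trees = boruta_trees)
    features <- selection$confirmed
    if (length(features) < 2L) {
      warning("fewer than 2 confirmed features; keeping all columns",
              call. = FALSE)
      features <- colnames(enc$x)
    }
  } else {
    features <- colnames(enc$x)
  }
  x <- enc$x[, features, drop = FALSE]
  y <- tab$label
  cv <- cv_oof(x, y, roster, folds = folds, seed = seed)
  meta <- fit_meta(cv$oof, y, seed = seed)
  oof_super <- meta_score(meta, cv$oof)
  threshold <- choose_threshold(oof_super, y)
  os <- oversample_indices(y, stage_seed(seed, "final_os"))
  base_models <- lapply(stats::setNames(names(roster), names(roster)),
                        function(b) fit_base(roster[[b]],
                                             x[os, , drop = FALSE], y[os],
                                             stage_seed(seed,
                                                        paste0("final_", b))))
  structure(list(
    roster = roster, features = features, selection = selection,
    imputer = imputer, base_models = base_models, meta = meta,
    threshold = threshold, oof = cv$oof, oof_super = oof_super,
    fold_assignment = cv$fold_assignment,
    train_ids = train_table$species_id, train_labels = y,
    partition_tag = partition_tag, seed = as.integer(seed)),
    class = "pe_stacked")
}

#' @export
print.pe_stacked <- function(x, ...) {
  cat(sprintf(
    "<pe_stacked> partition '%s': %d training species, %d features, threshold %.3f\n",
    x$partition_tag, length(x$train_ids), length(x$features), x$threshold))
  print(round(x$meta$coefficients, 4))
  invisible(x)
}

# Impute + encode a new table against a fitted model's training imputer.
encode_model_matrix <- function(model, table) {
  tab <- apply_imputer(model$imputer, table,
                       stage_seed(model$seed, "predict_imp"))
  enc <- encode_features(tab)
  missing_cols <- setdiff(model$features, colnames(enc$x))
  if (length(missing_cols)) {
    # one-hot levels absent from the new slice expand to all-zero columns
    blockish <- grepl("\\.", missing_cols)
    add <- matrix(0, nrow(enc$x), sum(blockish),
                  dimnames = list(NULL, missing_cols[blockish]))
    enc$x <- cbind(enc$x, add)
    still <- setdiff(model$features, colnames(enc$x))
    if (length(still)) {
      stop(sprintf("missing confirmed feature column(s): %s",
                   paste(still, collapse = ", ")), call. = FALSE)
    }
  }
  enc$x[, model$features, drop = FALSE]
}

predict_scores_matrix <- function(model, x) {
  scores <- vapply(model$base_models, predict_base, numeric(nrow(x)),
                   x = x)
  if (nrow(x) == 1L) scores <- matrix(scores, nrow = 1,
                                      dimnames = list(NULL,
                                                      names(model$base_models)))
  meta_score(model$meta, scores)
}

#' Predict PE scores for new species
#'
#' @param object A fitted `pe_stacked` model.
#' @param newdata Feature table rows to score.
#' @param ... Unused.
#' @return data.frame `species_id`, `pe_score` (probability of being
#'   threatened by extinction), `predicted_label` (threatened iff
#'   `pe_score >= threshold`), `partition_tag`.
#' @export
predict.pe_stacked <- function(object, newdata, ...) {
  x <- encode_model_matrix(object, newdata)
  pe <- predict_scores_matrix(object, x)
  data.frame(species_id = newdata$species_id, pe_score = pe,
             predicted_label = ifelse(pe >= object$threshold,
                                      "threatened", "not_threatened"),
             partition_tag = object$partition_tag,
             stringsAsFactors = FALSE)
}

#' Train the two dataset partitions
#'
#' Partition 1 trains one model on all training species; partition 2 trains
#' separate marine and non-marine models (feature selection is re-run on
#' each model's own training data). A partition-2 subset with fewer than 50
#' training rows is skipped with a warning.
#'
#' @param table Imputable feature table for all species.
#' @param split A [stratified_split()] assignment.
#' @param roster Base-learner roster.
#' @param seed Integer seed.
#' @param confirmed_all Optional precomputed confirmed features for the
#'   partition-1 (all-species) model; the marine / non-marine models always
#'   run selection on their own training data.
#' @param ... Passed to [train_stacked()].
#' @return List of class `pe_partitions` with elements `all`, and (when
#'   trainable) `marine`, `non_marine`.
#' @export
train_partitions <- function(table, split, roster = default_roster(),
                             seed = 1L, confirmed_all = NULL, ...) {
  train_ids <- split$species_id[split$role == "train"]
  train_tab <- table[table$species_id %in% train_ids, , drop = FALSE]
  models <- list()
  models$all <- train_stacked(train_tab, roster, seed = stage_seed(seed,
                                                                   "all"),
                              partition_tag = "all",
                              confirmed_features = confirmed_all, ...)
  for (part in c("marine", "non_marine")) {
    rows <- if (part == "marine") train_tab$dom_marine == 1L else
      train_tab$dom_marine == 0L
    sub <- train_tab[rows, , drop = FALSE]
    if (nrow(sub) < 50L || length(unique(sub$label)) < 2L) {
      warning(sprintf(
        "partition-2 subset '%s' has %d training rows; skipped",
        part, nrow(sub)), call. = FALSE)
      next
    }
    models[[part]] <- train_stacked(sub, roster,
                                    seed = stage_seed(seed, part),
                                    partition_tag = part, ...)
  }
  structure(models, class = "pe_partitions")
}

#' Score a table under partition 2 (marine + non-marine models)
#'
#' Marine rows are scored by the marine model, non-marine rows by the
#' non-marine model; if one of the two is missing its rows fall back to the
#' other (degenerate worlds).
#'
#' @param models A `pe_partitions` list.
#' @param table Feature table rows to score.
#' @return Prediction data.frame as in [predict.pe_stacked()], tagged
#'   `"marine"`/`"non_marine"`.
#' @export
predict_partition2 <- function(models, table) {
  marine_rows <- table$dom_marine == 1L
  parts <- list()
  m_model <- models$marine %||% models$non_marine
  n_model <- models$non_marine %||% models$marine
  if (any(marine_rows)) {
    parts$m <- predict(m_model, table[marine_rows, , drop = FALSE])
  }
  if (any(!marine_rows)) {
    parts$n <- predict(n_model, table[!marine_rows, , drop = FALSE])
  }
  out <- do.call(rbind, parts)
  out[order(out$species_id), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select the best dataset partition by mean per-class AUC
#'
#' For each partition, computes the AUC of its cross-validated
#' (out-of-fold) scores within every taxonomic class having at least five
#' labelled members and both labels present, then averages unweighted
#' across classes; the highest mean wins, ties going to `"all"`. If no
#' class reaches five members the pooled AUC decides.
#'
#' @param scores Named list (one element per partition) of data.frames
#'   with `score`, `label`, `class`.
#' @return List: `chosen` (partition name), `mean_auc` (named vector),
#'   `per_class` (data.frame partition, class, auc).
#' @export
select_partition <- function(scores) {
  stopifnot(length(scores) >= 2L)
  per_class <- list()
  mean_auc <- numeric(0)
  for (part in names(scores)) {
    df <- scores[[part]]
    cls_auc <- c()
    for (cl in sort(unique(df$class))) {
      sub <- df[df$class == cl, , drop = FALSE]
      if (nrow(sub) < 5L || length(unique(sub$label)) < 2L) next
      cls_auc[cl] <- auc(sub$score, sub$label)
      per_class[[length(per_class) + 1L]] <-
        data.frame(partition = part, class = cl, auc = cls_auc[cl])
    }
    mean_auc[part] <- if (length(cls_auc)) mean(cls_auc) else
      auc(df$score, df$label)   # fallback: pooled AUC
  }
  best <- max(mean_auc)
  chosen <- if ("all" %in% names(mean_auc) &&
                mean_auc[["all"]] >= best - 1e-12) "all" else
    names(mean_auc)[which.max(mean_auc)]
  list(chosen = chosen, mean_auc = mean_auc,
       per_class = if (length(per_class)) do.call(rbind, per_class) else
         NULL)
}
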