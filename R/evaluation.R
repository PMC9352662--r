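# Classifier evaluation: confusion-matrix metrics, threshold-independent
# rank metrics (AUC, AUC_PR, Gini), permutation variable importance, and
# validation on re-assessed formerly Data Deficient species.

#' Confusion matrix with threatened as the positive class
#'
#' @param predicted,reference Character vectors over
#'   `"threatened"` / `"not_threatened"`, equal length.
#' @return Object of class `pe_confusion`: integer `tp`, `tn`, `fp`, `fn`.
#' @export
confusion <- function(predicted, reference) {
  if (length(predicted) != length(reference)) {
    stop("predicted and reference label lists differ in length",
         call. = FALSE)
  }
  lv <- c("threatened", "not_threatened")
  stopifnot(all(predicted %in% lv), all(reference %in% lv))
  confusion_counts(tp = sum(predicted == "threatened" &
                              reference == "threatened"),
                   tn = sum(predicted == "not_threatened" &
                              reference == "not_threatened"),
                   fp = sum(predicted == "threatened" &
                              reference == "not_threatened"),
                   fn = sum(predicted == "not_threatened" &
                              reference == "threatened"))
}

#' Build a confusion matrix from its four counts
#' @param tp,tn,fp,fn Non-negative integer counts.
#' @return Object of class `pe_confusion`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  structure(list(tp = as.integer(tp), tn = as.integer(tn),
                 fp = as.integer(fp), fn = as.integer(fn)),
            class = "pe_confusion")
}

#' Pool confusion matrices by summing their counts
#' @param cms List of `pe_confusion` objects.
#' @return A pooled `pe_confusion`.
#' @export
pool_confusion <- function(cms) {
  confusion_counts(sum(vapply(cms, `[[`, integer(1), "tp")),
                   sum(vapply(cms, `[[`, integer(1), "tn")),
                   sum(vapply(cms, `[[`, integer(1), "fp")),
                   sum(vapply(cms, `[[`, integer(1), "fn")))
}

#' @export
print.pe_confusion <- function(x, ...) {
  m <- matrix(c(x$tn, x$fn, x$fp, x$tp), 2, 2,
              dimnames = list(predicted = c("not_threatened", "threatened"),
                              reference = c("not_threatened", "threatened")))
  print(m)
  invisible(x)
}

#' Threshold-dependent performance metrics from a confusion matrix
#'
#' Accuracy, specificity, sensitivity (recall), false positive rate,
#' negative and positive predictive value, and balanced accuracy (the mean
#' of specificity and sensitivity). Metrics with a zero denominator are
#' returned as `NA` (undefined), never coerced to 0.
#'
#' @param cm A `pe_confusion`.
#' @return Named list of metrics at full precision.
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "pe_confusion"))
  tp <- cm$tp; tn <- cm$tn; fp <- cm$fp; fn <- cm$fn
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  specificity <- frac(tn, tn + fp)
  sensitivity <- frac(tp, tp + fn)
  list(
    accuracy = frac(tp + tn, tp + tn + fp + fn),
    specificity = specificity,
    sensitivity = sensitivity,
    false_positive_rate = frac(fp, fp + tn),
    npv = frac(tn, tn + fn),
    ppv = frac(tp, tp + fp),
    balanced_accuracy = if (is.na(specificity) || is.na(sensitivity))
      NA_real_ else (specificity + sensitivity) / 2)
}

#' Round half-up for metric display
#'
#' `round()` in R rounds half to even; tabulated metrics use conventional
#' half-up rounding at 2 decimal places.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Area under the ROC curve (rank statistic)
#'
#' The probability that a uniformly chosen positive outranks a uniformly
#' chosen negative, ties counting one half — the Mann-Whitney formulation,
#' invariant under strictly monotone score transforms.
#'
#' @param scores Numeric scores (higher = more likely threatened).
#' @param labels Labels; `"threatened"`/1/TRUE is positive.
#' @return AUC in `[0, 1]`; `NA` if only one class is present.
#' @export
auc <- function(scores, labels) {
  y <- as_binary_label(labels)
  np <- sum(y == 1L); nn <- sum(y == 0L)
  if (np == 0L || nn == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision over distinct score cut-points (no linear
#' interpolation between PR points): `sum_k (R_k - R_{k-1}) * P_k`.
#'
#' @inheritParams auc
#' @return AUC_PR in `(0, 1]`; `NA` if there are no positives.
#' @export
auc_pr <- function(scores, labels) {
  y <- as_binary_label(labels)
  np <- sum(y == 1L)
  if (np == 0L) return(NA_real_)
  o <- order(scores, decreasing = TRUE)
  y <- y[o]; s <- scores[o]
  cum_tp <- cumsum(y)
  cum_pp <- seq_along(y)
  last <- cum_pp[!duplicated(s, fromLast = TRUE)]  # end of each tie group
  prec <- cum_tp[last] / cum_pp[last]
  rec <- cum_tp[last] / np
  sum(diff(c(0, rec)) * prec)
}

#' Gini coefficient of class separation
#'
#' `2 * AUC - 1`: 0 for no separation, 1 for perfect separation.
#' @inheritParams auc
#' @return Gini in `[-1, 1]`.
#' @export
gini <- function(scores, labels) {
  2 * auc(scores, labels) - 1
}

as_binary_label <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    stopifnot(all(labels %in% c(0, 1)))
    return(as.integer(labels))
  }
  stopifnot(all(labels %in% c("threatened", "not_threatened")))
  as.integer(labels == "threatened")
}

#' Permutation variable importance of a stacked model
#'
#' For each feature column, the mean over `reps` seeded permutations of
#' (baseline test AUC - AUC after permuting that column); the baseline is
#' computed once. Features the model never uses get importance near zero.
#'
#' @param model A fitted `pe_stacked` model.
#' @param test_table Feature table of test rows (with `label`).
#' @param reps Number of permutation repetitions per feature.
#' @param seed Integer seed.
#' @param features Columns to assess (default: the model's confirmed
#'   feature columns).
#' @return data.frame `feature`, `importance`, sorted descending.
#' @export
permutation_importance <- function(model, test_table, reps = 50, seed = 1L,
                                   features = NULL) {
  stopifnot(inherits(model, "pe_stacked"))
  y <- test_table$label
  if (length(unique(y[!is.na(y)])) < 2L) {
    stop("test set must contain both classes", call. = FALSE)
  }
  enc <- encode_model_matrix(model, test_table)
  base_scores <- predict_scores_matrix(model, enc)
  baseline <- auc(base_scores, y)
  if (is.null(features)) features <- model$features
  features <- intersect(features, colnames(enc))
  n <- nrow(enc)
  imp <- numeric(length(features))
  set.seed(stage_seed(seed, "perm_importance"))
  for (j in seq_along(features)) {
    # stack all repetitions into one matrix so each base learner predicts
    # once per feature rather than once per repetition
    big <- enc[rep(seq_len(n), reps), , drop = FALSE]
    col <- unlist(lapply(seq_len(reps), function(r)
      enc[sample.int(n), features[j]]))
    big[, features[j]] <- col
    scores <- predict_scores_matrix(model, big)
    loss <- vapply(seq_len(reps), function(r) {
      baseline - auc(scores[((r - 1L) * n + 1L):(r * n)], y)
    }, numeric(1))
    imp[j] <- mean(loss)
  }
  out <- data.frame(feature = features, importance = imp,
                    stringsAsFactors = FALSE)
  out[order(-out$importance), , drop = FALSE]
}

#' Validate a model on re-assessed formerly Data Deficient species
#'
#' The synthetic analogue of scoring species that were Data Deficient at
#' training time and later received a Red List category: their revealed
#' labels are compared with the model's predictions. Errors if any row
#' overlaps the model's training set.
#'
#' @param model A fitted `pe_stacked` model.
#' @param reassessed_table Feature table rows that were DD holdouts, with
#'   `label` now filled with the revealed category labels.
#' @return List with `confusion`, `metrics`, `n_correct`, `n`.
#' @export
validate_on_reassessed <- function(model, reassessed_table) {
  stopifnot(inherits(model, "pe_stacked"))
  if (nrow(reassessed_table) == 0L) {
    stop("empty re-assessed validation slice", call. = FALSE)
  }
  overlap <- intersect(reassessed_table$species_id, model$train_ids)
  if (length(overlap)) {
    stop(sprintf("re-assessed species overlap the training set: %s",
                 paste(utils::head(overlap, 5L), collapse = ", ")),
         call. = FALSE)
  }
  if (anyNA(reassessed_table$label)) {
    stop("re-assessed rows must carry revealed labels", call. = FALSE)
  }
  pred <- predict(model, reassessed_table)
  cm <- confusion(pred$predicted_label, reassessed_table$label)
  list(confusion = cm, metrics = compute_metrics(cm),
       n_correct = cm$tp + cm$tn, n = cm$tp + cm$tn + cm$fp + cm$fn)
}
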