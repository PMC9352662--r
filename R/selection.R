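# Shadow-feature (Boruta-style) relevance filtering: each feature competes
# against permuted copies of all features across repeated randomized-tree
# fits; hits are aggregated with a two-sided binomial test.

#' One shadow-feature run
#'
#' Every feature is duplicated and independently permuted (the shadows); a
#' seeded randomized-tree ensemble is fitted on originals + shadows with
#' out-of-bag permutation importance. A feature scores a hit iff its
#' importance strictly exceeds the maximum shadow importance.
#'
#' @param x Numeric feature matrix (>= 2 columns).
#' @param y Binary label vector/factor with both classes present.
#' @param seed Integer seed.
#' @param num_trees Trees in the ensemble.
#' @return Named logical vector of per-feature hit indicators.
#' @export
shadow_run <- function(x, y, seed, num_trees = 64L) {
  if (ncol(x) < 2L) stop("need at least 2 features", call. = FALSE)
  y <- factor(y)
  if (nlevels(y) < 2L) stop("label is constant", call. = FALSE)
  n <- nrow(x)
  orig_names <- colnames(x)
  # canonical column order + per-column-seeded shadow permutations make the
  # run invariant to the order of the feature columns
  x <- x[, order(orig_names), drop = FALSE]
  shadows <- vapply(colnames(x), function(cn) {
    perm <- with_seed(stage_seed(seed, paste0("shadow_", cn)),
                      sample.int(n))
    x[perm, cn]
  }, numeric(n))
  colnames(shadows) <- paste0("shadow__", colnames(x))
  df <- as.data.frame(cbind(x, shadows))
  names(df) <- make.names(names(df), unique = TRUE)
  fit <- ranger::ranger(
    y = y, x = df, num.trees = num_trees,
    importance = "permutation", seed = stage_seed(seed, "ranger"),
    num.threads = 1L, respect.unordered.factors = "order")
  imp <- fit$variable.importance
  n_orig <- ncol(x)
  orig_imp <- imp[seq_len(n_orig)]
  shadow_imp <- imp[(n_orig + 1L):length(imp)]
  hits <- orig_imp > max(shadow_imp)
  names(hits) <- colnames(x)
  hits[orig_names]
}

#' Boruta-style feature selection
#'
#' Aggregates `R` seeded [shadow_run()]s (one-shot variant: all features
#' stay in every run) and classifies each feature by a two-sided binomial
#' test of its hit count against Binomial(R, 1/2) at level `alpha`:
#' significantly more hits than R/2 confirms, significantly fewer rejects,
#' anything else is tentative. One-hot blocks are confirmed if any member
#' column is confirmed. Only confirmed features feed downstream models.
#'
#' @param x Numeric feature matrix.
#' @param y Binary labels.
#' @param R Number of runs (default 50).
#' @param alpha Significance level (default 0.01, i.e. 99% confidence).
#' @param seed Integer seed.
#' @param blocks Optional character vector mapping each column of `x` to a
#'   source-feature block.
#' @param num_trees Trees per run.
#' @return Object of class `pe_selection`: data.frame `result` (feature,
#'   hits, decision), `confirmed` (confirmed column names), `blocks`
#'   (block-level decisions), `R`, `alpha`.
#' @export
boruta_select <- function(x, y, R = 50L, alpha = 0.01, seed = 1L,
                          blocks = NULL, num_trees = 64L) {
  stopifnot(R >= 1L)
  hits <- integer(ncol(x))
  for (r in seq_len(R)) {
    hits <- hits + shadow_run(x, y, seed = stage_seed(seed,
                                                      paste0("run", r)),
                              num_trees = num_trees)
  }
  decision <- vapply(hits, boruta_decision, "", R = R, alpha = alpha)
  result <- data.frame(feature = colnames(x), hits = hits,
                       decision = decision, stringsAsFactors = FALSE)
  confirmed <- result$feature[result$decision == "confirmed"]
  block_tab <- NULL
  if (!is.null(blocks)) {
    stopifnot(length(blocks) == ncol(x))
    confirmed_blocks <- unique(blocks[result$decision == "confirmed"])
    # a block is confirmed if any member is; confirmed columns then include
    # the whole block so categorical features stay intact
    confirmed <- result$feature[blocks %in% confirmed_blocks]
    agg <- function(b) {
      d <- result$decision[blocks == b]
      if (any(d == "confirmed")) "confirmed"
      else if (all(d == "rejected")) "rejected" else "tentative"
    }
    ub <- unique(blocks)
    block_tab <- data.frame(block = ub,
                            decision = vapply(ub, agg, ""),
                            stringsAsFactors = FALSE)
  }
  structure(list(result = result, confirmed = confirmed,
                 blocks = block_tab, R = R, alpha = alpha),
            class = "pe_selection")
}

# Two-sided exact binomial decision for a hit count.
boruta_decision <- function(h, R, alpha) {
  p_hi <- stats::pbinom(h - 1L, R, 0.5, lower.tail = FALSE)
  p_lo <- stats::pbinom(h, R, 0.5)
  p <- min(1, 2 * min(p_hi, p_lo))
  if (p <= alpha && h > R / 2) "confirmed"
  else if (p <= alpha && h < R / 2) "rejected"
  else "tentative"
}

#' @export
print.pe_selection <- function(x, ...) {
  tab <- table(factor(x$result$decision,
                      c("confirmed", "tentative", "rejected")))
  cat(sprintf("<pe_selection> R = %d, alpha = %g: %d confirmed, %d tentative, %d rejected\n",
              x$R, x$alpha, tab[1], tab[2], tab[3]))
  invisible(x)
}

#' Run shadow-feature selection on a feature table
#'
#' Convenience wrapper: one-hot encodes the table (see [encode_features()])
#' and runs [boruta_select()] with block-level aggregation.
#'
#' @param table A feature table with `label` filled for all rows used.
#' @inheritParams boruta_select
#' @return A `pe_selection`.
#' @export
select_features <- function(table, R = 50L, alpha = 0.01, seed = 1L,
                            num_trees = 64L) {
  stopifnot(!anyNA(table$label))
  enc <- encode_features(table)
  boruta_select(enc$x, table$label, R = R, alpha = alpha, seed = seed,
                blocks = enc$blocks, num_trees = num_trees)
}
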