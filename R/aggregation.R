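# Spatial aggregation of PE scores: per-cell fraction of Data Deficient
# species predicted threatened, and percent change in mean PE score when
# DD species are pooled with data-sufficient species.

#' Per-cell fraction of DD species predicted threatened
#'
#' For each grid cell: (number of DD species whose range includes the cell
#' and whose prediction is threatened) / (number of DD species present).
#' Cells with no DD species are masked (`NA`), never zero.
#'
#' @param predictions Prediction data.frame (`species_id`,
#'   `predicted_label`) for the DD species.
#' @param range_cells Named list (species_id) of range cell ids.
#' @param grid A [grid_spec()].
#' @return List: `frac` (length `n_cells`, NA-masked), `n_dd`,
#'   `n_dd_threatened` (integer vectors).
#' @export
fraction_dd_threatened <- function(predictions, range_cells, grid) {
  assert_grid(grid)
  miss <- setdiff(predictions$species_id, names(range_cells))
  if (length(miss)) {
    stop(sprintf("DD species without range cells: %s",
                 paste(utils::head(miss, 5L), collapse = ", ")),
         call. = FALSE)
  }
  rc <- range_cells[predictions$species_id]
  tab0 <- function(cells) tabulate(c(cells, integer(0)),
                                   nbins = grid$n_cells)
  n_dd <- tab0(unlist(rc, use.names = FALSE))
  thr <- predictions$predicted_label == "threatened"
  n_thr <- tab0(unlist(rc[thr], use.names = FALSE))
  frac <- ifelse(n_dd > 0L, n_thr / pmax(n_dd, 1L), NA_real_)
  list(frac = frac, n_dd = n_dd, n_dd_threatened = n_thr)
}

#' Percent change in mean PE score when DD species are included
#'
#' Per cell: the mean PE score over data-sufficient species present, the
#' mean over DS and DD species pooled, and the relative change
#' `100 * (mean_all - mean_ds) / mean_ds`. Data-sufficient species
#' contribute their model-predicted PE score (not a 0/1 derived from their
#' category). Cells without DS species are masked.
#'
#' @param predictions_ds,predictions_dd Prediction data.frames
#'   (`species_id`, `pe_score`) for DS and DD species.
#' @param range_cells Named list (species_id) of range cell ids.
#' @param grid A [grid_spec()].
#' @return List: `mean_pe_ds`, `mean_pe_all`, `pct_change` (NA-masked),
#'   `n_ds`, `n_dd`.
#' @export
percent_change_map <- function(predictions_ds, predictions_dd, range_cells,
                               grid) {
  assert_grid(grid)
  acc <- function(pred) {
    rc <- range_cells[pred$species_id]
    cells <- c(unlist(rc, use.names = FALSE), integer(0))
    w <- rep(pred$pe_score, lengths(rc))
    n <- tabulate(cells, nbins = grid$n_cells)
    s <- numeric(grid$n_cells)
    if (length(cells)) {
      agg <- rowsum(w, cells)
      s[as.integer(rownames(agg))] <- agg[, 1]
    }
    list(n = n, s = s)
  }
  ds <- acc(predictions_ds)
  dd <- acc(predictions_dd)
  mean_ds <- ifelse(ds$n > 0L, ds$s / pmax(ds$n, 1L), NA_real_)
  n_all <- ds$n + dd$n
  mean_all <- ifelse(n_all > 0L, (ds$s + dd$s) / pmax(n_all, 1L),
                     NA_real_)
  pct <- ifelse(!is.na(mean_ds) & mean_ds > 0 & !is.na(mean_all),
                100 * (mean_all - mean_ds) / mean_ds, NA_real_)
  list(mean_pe_ds = mean_ds, mean_pe_all = mean_all, pct_change = pct,
       n_ds = ds$n, n_dd = dd$n)
}

#' Per-taxonomic-class summary of DD predictions
#'
#' For each taxonomic class with at least one DD species: the number of DD
#' species, how many are predicted threatened, and the fraction; plus the
#' combined threatened fraction before (DS only, by reference label) and
#' after including the DD predictions.
#'
#' @param predictions Prediction data.frame for DD species
#'   (`species_id`, `predicted_label`).
#' @param species Species table with `species_id`, `class`, `category`.
#' @return data.frame, one row per class with DD species.
#' @export
per_class_summary <- function(predictions, species) {
  sp <- species[match(predictions$species_id, species$species_id), ]
  dd <- data.frame(class = sp$class,
                   thr = predictions$predicted_label == "threatened")
  lab <- binarize_category(species$category)
  ds <- data.frame(class = species$class, lab = lab)[
    lab %in% c("threatened", "not_threatened"), ]
  out <- list()
  for (cl in sort(unique(dd$class))) {
    d <- dd[dd$class == cl, , drop = FALSE]
    s <- ds[ds$class == cl, , drop = FALSE]
    n_ds_thr <- sum(s$lab == "threatened")
    out[[cl]] <- data.frame(
      class = cl,
      n_dd = nrow(d),
      n_dd_predicted_threatened = sum(d$thr),
      frac_dd_threatened = mean(d$thr),
      frac_threatened_ds = if (nrow(s)) n_ds_thr / nrow(s) else NA_real_,
      frac_threatened_with_dd = (n_ds_thr + sum(d$thr)) /
        (nrow(s) + nrow(d)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
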