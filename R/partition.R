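# Binary reclassification of Red List categories, exclusion rules and the
# stratified 75/25 train/test split with minority oversampling.

#' Reclassify a Red List category into the binary threat label
#'
#' VU, EN and CR are threatened; LC, LR/LC, LR/CD and NT are not
#' threatened; DD is held out; EX and EW are excluded from the analysis.
#'
#' @param category Character vector of Red List codes.
#' @return Character vector over `"threatened"`, `"not_threatened"`,
#'   `"dd"`, `"excluded"`.
#' @export
binarize_category <- function(category) {
  map <- c(VU = "threatened", EN = "threatened", CR = "threatened",
           LC = "not_threatened", `LR/LC` = "not_threatened",
           `LR/CD` = "not_threatened", NT = "not_threatened",
           DD = "dd", EX = "excluded", EW = "excluded")
  out <- unname(map[category])
  if (anyNA(out)) {
    bad <- unique(category[is.na(out)])
    stop(sprintf("unknown Red List category code(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  out
}

#' Remove outdated assessments, keeping small classes viable
#'
#' Species flagged as having an outdated assessment are removed, unless
#' removal would leave their taxonomic class with fewer than five records;
#' in that case outdated records of the class are added back in
#' lexicographic `species_id` order until the class reaches five records or
#' none remain.
#'
#' @param species Species table with columns `species_id`, `class`,
#'   `outdated_assessment`.
#' @return The retained subset (row order preserved).
#' @export
apply_outdated_rule <- function(species) {
  keep <- !species$outdated_assessment
  for (cl in unique(species$class)) {
    in_cl <- species$class == cl
    n_fresh <- sum(in_cl & keep)
    if (n_fresh >= 5L) next
    outdated_ids <- sort(species$species_id[in_cl & !keep])
    n_back <- min(5L - n_fresh, length(outdated_ids))
    if (n_back > 0L) {
      keep[species$species_id %in% outdated_ids[seq_len(n_back)]] <- TRUE
    }
  }
  species[keep, , drop = FALSE]
}

#' Stratified 75/25 train/test split
#'
#' Strata are the cross of taxonomic family and the marine flag; within
#' each (family, marine, label) cell species are shuffled (seeded) and
#' allocated so that the global train fraction hits 75% exactly up to
#' rounding, using largest-remainder apportionment over cells with ties
#' broken by stratum id. Singleton cells go to train. DD species are
#' assigned `dd_holdout`; EX/EW are `excluded`.
#'
#' @param species Species table with `species_id`, `family`, `marine`,
#'   `category`.
#' @param seed Integer seed.
#' @param train_fraction Defaults to 0.75.
#' @return data.frame of class `pe_split`: `species_id`, `role`
#'   (train/test/dd_holdout/excluded), `stratum_id`, `label`.
#' @export
stratified_split <- function(species, seed, train_fraction = 0.75) {
  lab <- binarize_category(species$category)
  out <- data.frame(species_id = species$species_id,
                    role = NA_character_,
                    stratum_id = paste(species$family,
                                       ifelse(species$marine, "marine",
                                              "non_marine"), sep = "|"),
                    label = lab, stringsAsFactors = FALSE)
  out$role[lab == "dd"] <- "dd_holdout"
  out$role[lab == "excluded"] <- "excluded"
  lab_rows <- which(lab %in% c("threatened", "not_threatened"))
  if (length(lab_rows) < 2L) stop("need at least 2 labelled species",
                                  call. = FALSE)
  cell_id <- paste(out$stratum_id[lab_rows], lab[lab_rows], sep = "|")
  cells <- split(lab_rows, cell_id)
  cells <- cells[order(names(cells))]
  k <- lengths(cells)
  singleton <- k == 1L
  quota <- train_fraction * k
  base <- ifelse(singleton, 1L, floor(quota))
  total_target <- round(train_fraction * length(lab_rows))
  seats <- total_target - sum(base)
  if (seats > 0L) {
    rem <- quota - floor(quota)
    rem[singleton] <- -1          # already fully allocated
    ord <- order(-rem, names(cells))   # largest remainder, tie by cell id
    ord <- ord[!singleton[ord]]
    # give one extra seat each to the `seats` cells with largest remainder
    take <- integer(0)
    for (i in ord) {
      if (length(take) >= seats) break
      if (base[i] + 1L <= k[i]) take <- c(take, i)
    }
    base[take] <- base[take] + 1L
  } else if (seats < 0L) {
    # remove seats from smallest remainders (rare; singleton-heavy tables)
    rem <- quota - floor(quota)
    ord <- order(rem, names(cells))
    ord <- ord[!singleton[ord] & base[ord] > 0L]
    take <- utils::head(ord, -seats)
    base[take] <- base[take] - 1L
  }
  with_seed(stage_seed(seed, "split"), {
    for (i in seq_along(cells)) {
      rows <- cells[[i]]
      rows <- rows[order(out$species_id[rows])]
      perm <- if (length(rows) > 1L) sample(rows) else rows
      n_tr <- base[i]
      out$role[perm[seq_len(n_tr)]] <- "train"
      if (n_tr < length(perm)) {
        out$role[perm[(n_tr + 1L):length(perm)]] <- "test"
      }
    }
  })
  if (any(singleton)) {
    message(sprintf("%d singleton stratum cell(s) assigned to train",
                    sum(singleton)))
  }
  class(out) <- c("pe_split", "data.frame")
  out
}

#' Oversample the minority class to balance a training set
#'
#' Duplicates seeded draws (with replacement) of minority-class rows until
#' both classes have equal counts. Intended to be applied inside each
#' cross-validation training fold only — never to validation folds or the
#' test set.
#'
#' @param train_rows data.frame with a `label` column holding exactly the
#'   two classes.
#' @param seed Integer seed.
#' @return The row-augmented data.frame (original rows first).
#' @export
oversample_minority <- function(train_rows, seed) {
  idx <- oversample_indices(train_rows$label, seed)
  out <- train_rows[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Index-level version used inside CV folds.
oversample_indices <- function(labels, seed) {
  tab <- table(labels)
  if (length(tab) < 2L) stop("oversampling requires both classes",
                             call. = FALSE)
  if (length(tab) > 2L) stop("more than two classes in training labels",
                             call. = FALSE)
  n <- length(labels)
  if (tab[1] == tab[2]) return(seq_len(n))
  minority <- names(tab)[which.min(tab)]
  need <- abs(diff(as.integer(tab)))
  pool <- which(labels == minority)
  extra <- with_seed(stage_seed(seed, "oversample"),
                     sample(pool, need, replace = TRUE))
  c(seq_len(n), extra)
}
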