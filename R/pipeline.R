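# Staged, manifest-tracked orchestration: simulate -> extract -> split ->
# select -> train -> evaluate -> aggregate. A run is a pure function of
# (config, seed): identical configs give hash-identical outputs.

PIPELINE_STAGES <- c("simulate", "extract", "split", "select", "train",
                     "evaluate", "aggregate")

#' Default pipeline configuration
#'
#' World parameters (see [world_params()]), pipeline parameters (CV folds,
#' selection runs and level, permutation-importance repetitions, base
#' roster sizes) and the global seed.
#'
#' @param ... Named overrides; nested world parameters go under `world`.
#' @return Named list of class `pe_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    world = world_params(),
    folds = 10L,
    boruta_R = 50L,
    boruta_alpha = 0.01,
    boruta_trees = 64L,
    importance_reps = 50L,
    train_fraction = 0.75,
    reassess_fraction = 0.1)  # DD holdouts revealed for validation
  ov <- list(...)
  if (!is.null(ov$world)) {
    cfg$world[names(ov$world)] <- ov$world
    ov$world <- NULL
  }
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) {
    stop(sprintf("unknown config field(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  cfg[names(ov)] <- ov
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("pe_config", "list")
  cfg
}

#' Load a pipeline configuration from a YAML file
#'
#' Any field present in the file overrides the default; `world:` holds the
#' world-generation parameters.
#'
#' @param path YAML file path.
#' @param ... Further overrides applied after the file.
#' @return A `pe_config`.
#' @export
load_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(default_config, raw)
  ov <- list(...)
  if (length(ov)) {
    raw2 <- cfg
    class(raw2) <- "list"
    raw2[names(ov)] <- ov
    cfg <- do.call(default_config, raw2)
  }
  cfg
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = 12), tmp)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(outdir, stage, config, inputs, outputs,
                           elapsed) {
  man <- list(stage = stage, seed = config$seed,
              config_md5 = config_hash(config),
              inputs = as.list(tools::md5sum(inputs)),
              outputs = as.list(tools::md5sum(outputs)),
              elapsed_sec = round(elapsed, 3),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(outdir, sprintf("manifest_%s.json", stage))
  writeLines(jsonlite::toJSON(man, auto_unbox = TRUE, pretty = TRUE),
             path)
  path
}

require_artifact <- function(outdir, files, needed_by, produced_by) {
  paths <- file.path(outdir, files)
  miss <- paths[!file.exists(paths)]
  if (length(miss)) {
    stop(sprintf(
      "stage '%s' needs missing artifact(s) %s; run stage '%s' first",
      needed_by, paste(basename(miss), collapse = ", "), produced_by),
      call. = FALSE)
  }
  paths
}

#' Run one pipeline stage
#'
#' Stages read their upstream artifacts from `outdir` and write their own
#' outputs plus a JSON manifest (seed, config hash, input/output md5 sums,
#' wall time). Missing upstream artifacts raise an error naming the stage
#' to run.
#'
#' @param stage One of `simulate`, `extract`, `split`, `select`, `train`,
#'   `evaluate`, `aggregate`.
#' @param config A [default_config()] list.
#' @param outdir Run directory.
#' @return Invisibly, the list of files written.
#' @export
run_stage <- function(stage, config, outdir) {
  stage <- match.arg(stage, PIPELINE_STAGES)
  stopifnot(inherits(config, "pe_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  fn <- get(paste0("stage_", gsub("-", "_", stage)), mode = "function")
  res <- fn(config, outdir)
  elapsed <- proc.time()[["elapsed"]] - t0
  write_manifest(outdir, stage, config, res$inputs, res$outputs, elapsed)
  message(sprintf("[%s] done in %.1fs (%d files)", stage, elapsed,
                  length(res$outputs)))
  invisible(res$outputs)
}

#' Run the whole pipeline
#'
#' @inheritParams run_stage
#' @return Invisibly, `outdir`.
#' @export
run_pipeline <- function(config, outdir) {
  for (stage in PIPELINE_STAGES) run_stage(stage, config, outdir)
  invisible(outdir)
}

stage_simulate <- function(config, outdir) {
  world <- generate_world(config$world, config$seed)
  wd <- file.path(outdir, "world")
  write_world(world, wd)
  outs <- c(list.files(wd, recursive = TRUE, full.names = TRUE))
  list(inputs = character(0), outputs = outs)
}

stage_extract <- function(config, outdir) {
  ins <- require_artifact(outdir, "world/world_manifest.json", "extract",
                          "simulate")
  world <- read_world(file.path(outdir, "world"))
  tab <- assemble_feature_table(world$species, world$occurrences,
                                world$layers, world$grid,
                                ranges = world$ranges,
                                range_cells = world$range_cells)
  f1 <- file.path(outdir, "features.csv")
  data.table::fwrite(as.data.frame(tab), f1)
  f2 <- file.path(outdir, "feature_columns.csv")
  data.table::fwrite(attr(tab, "column_manifest"), f2)
  list(inputs = ins, outputs = c(f1, f2))
}

stage_split <- function(config, outdir) {
  ins <- require_artifact(outdir, "world/species.csv", "split", "simulate")
  species <- as.data.frame(data.table::fread(ins[1]))
  species <- apply_outdated_rule(species)
  split <- stratified_split(species, config$seed,
                            train_fraction = config$train_fraction)
  f <- file.path(outdir, "split.csv")
  data.table::fwrite(split, f)
  list(inputs = ins, outputs = f)
}

load_features <- function(outdir) {
  tab <- as.data.frame(data.table::fread(
    file.path(outdir, "features.csv"),
    na.strings = c("NA", "")))
  tab$label[tab$label == ""] <- NA
  class(tab) <- c("pe_features", "data.frame")
  tab
}

stage_select <- function(config, outdir) {
  ins <- require_artifact(outdir, c("features.csv", "split.csv"),
                          "select", "extract (and split)")
  tab <- load_features(outdir)
  split <- as.data.frame(data.table::fread(file.path(outdir, "split.csv")))
  train_tab <- tab[tab$species_id %in%
                     split$species_id[split$role == "train"], ]
  train_tab <- impute_missing(train_tab, stage_seed(config$seed,
                                                    "select_imp"))
  sel <- select_features(train_tab, R = config$boruta_R,
                         alpha = config$boruta_alpha,
                         seed = stage_seed(config$seed, "select"),
                         num_trees = config$boruta_trees)
  f <- file.path(outdir, "selection.csv")
  data.table::fwrite(sel$result, f)
  f2 <- file.path(outdir, "selection_blocks.csv")
  data.table::fwrite(sel$blocks, f2)
  f3 <- file.path(outdir, "selection_confirmed.csv")
  data.table::fwrite(data.frame(feature = sel$confirmed), f3)
  list(inputs = ins, outputs = c(f, f2, f3))
}

stage_train <- function(config, outdir) {
  ins <- require_artifact(outdir, c("features.csv", "split.csv"),
                          "train", "extract (and split)")
  tab <- load_features(outdir)
  split <- as.data.frame(data.table::fread(file.path(outdir, "split.csv")))
  split <- split[match(tab$species_id, split$species_id), ]
  # the select stage already ran on exactly the partition-1 training data;
  # reuse its confirmed features for the all-species model
  conf_file <- file.path(outdir, "selection_confirmed.csv")
  confirmed_all <- if (file.exists(conf_file))
    data.table::fread(conf_file)$feature else NULL
  models <- train_partitions(
    tab, split, roster = default_roster(),
    seed = stage_seed(config$seed, "train"),
    confirmed_all = confirmed_all,
    folds = config$folds, boruta_R = config$boruta_R,
    boruta_alpha = config$boruta_alpha,
    boruta_trees = config$boruta_trees)
  # score every retained species (train rows only for map-making; test and
  # DD rows are the evaluation/prediction populations)
  score_tab <- tab[!is.na(split$role) & split$role != "excluded", ]
  pred1 <- predict(models$all, score_tab)
  preds <- list(pred1)
  if (!is.null(models$marine) || !is.null(models$non_marine)) {
    preds <- c(preds, list(predict_partition2(models, score_tab)))
  }
  pred <- do.call(rbind, preds)
  f <- file.path(outdir, "predictions.csv")
  data.table::fwrite(pred, f)
  # out-of-fold super-learner scores per partition for partition choice
  oof_rows <- list()
  sp_class <- tab$class[match(models$all$train_ids, tab$species_id)]
  oof_rows$all <- data.frame(partition = "all",
                             species_id = models$all$train_ids,
                             score = models$all$oof_super,
                             label = models$all$train_labels,
                             class = sp_class)
  for (part in c("marine", "non_marine")) {
    m <- models[[part]]
    if (is.null(m)) next
    oof_rows[[part]] <- data.frame(
      partition = "partition2", species_id = m$train_ids,
      score = m$oof_super, label = m$train_labels,
      class = tab$class[match(m$train_ids, tab$species_id)])
  }
  oof_df <- do.call(rbind, oof_rows)
  f2 <- file.path(outdir, "oof_scores.csv")
  data.table::fwrite(oof_df, f2)
  mi <- file.path(outdir, "model_info.json")
  writeLines(jsonlite::toJSON(list(
    partitions = names(models),
    thresholds = lapply(models, `[[`, "threshold"),
    meta_coefficients = lapply(models, function(m) m$meta$coefficients),
    n_confirmed = lapply(models, function(m) length(m$features)),
    seeds = lapply(models, `[[`, "seed")),
    auto_unbox = TRUE, pretty = TRUE, digits = 10), mi)
  saveRDS(models, file.path(outdir, "models.rds"))
  list(inputs = ins, outputs = c(f, f2, mi))
}

stage_evaluate <- function(config, outdir) {
  ins <- require_artifact(outdir, c("predictions.csv", "split.csv",
                                    "features.csv", "models.rds"),
                          "evaluate", "train")
  tab <- load_features(outdir)
  split <- as.data.frame(data.table::fread(file.path(outdir, "split.csv")))
  pred <- as.data.frame(data.table::fread(
    file.path(outdir, "predictions.csv")))
  models <- readRDS(file.path(outdir, "models.rds"))
  oof_df <- as.data.frame(data.table::fread(
    file.path(outdir, "oof_scores.csv")))
  parts <- split(oof_df[c("score", "label", "class")], oof_df$partition)
  choice <- if (length(parts) >= 2L) select_partition(parts) else
    list(chosen = names(parts), mean_auc = NULL, per_class = NULL)
  test_ids <- split$species_id[split$role == "test"]
  test_tab <- tab[tab$species_id %in% test_ids, ]
  p1 <- pred[pred$partition_tag == "all" &
               pred$species_id %in% test_ids, ]
  p1 <- p1[match(test_tab$species_id, p1$species_id), ]
  cm <- confusion(p1$predicted_label, test_tab$label)
  metrics <- compute_metrics(cm)
  metrics$auc <- auc(p1$pe_score, test_tab$label)
  metrics$auc_pr <- auc_pr(p1$pe_score, test_tab$label)
  metrics$gini <- gini(p1$pe_score, test_tab$label)
  f1 <- file.path(outdir, "metrics.csv")
  data.table::fwrite(data.frame(metric = names(metrics),
                                value = unlist(metrics),
                                partition = "all", slice = "test"), f1)
  imp <- permutation_importance(models$all, test_tab,
                                reps = config$importance_reps,
                                seed = stage_seed(config$seed, "importance"))
  f2 <- file.path(outdir, "importance.csv")
  data.table::fwrite(imp, f2)
  f3 <- file.path(outdir, "partition_choice.json")
  writeLines(jsonlite::toJSON(choice, auto_unbox = TRUE, pretty = TRUE,
                              digits = 10), f3)
  # reveal labels for a DD subset, emulating a later Red List update
  world_sp <- as.data.frame(data.table::fread(
    file.path(outdir, "world", "species.csv")))
  dd_ids <- split$species_id[split$role == "dd_holdout"]
  n_rev <- round(config$reassess_fraction * length(dd_ids))
  outs <- c(f1, f2, f3)
  if (n_rev >= 2L) {
    rev_ids <- with_seed(stage_seed(config$seed, "reassess"),
                         sort(sample(dd_ids, n_rev)))
    rev_tab <- tab[tab$species_id %in% rev_ids, ]
    truth <- world_sp$true_threatened[match(rev_tab$species_id,
                                            world_sp$species_id)]
    rev_tab$label <- ifelse(truth, "threatened", "not_threatened")
    val <- validate_on_reassessed(models$all, rev_tab)
    f4 <- file.path(outdir, "reassessed_validation.json")
    writeLines(jsonlite::toJSON(list(
      n = val$n, n_correct = val$n_correct,
      confusion = unclass(val$confusion), metrics = val$metrics),
      auto_unbox = TRUE, pretty = TRUE, digits = 10), f4)
    outs <- c(outs, f4)
  }
  list(inputs = ins, outputs = outs)
}

stage_aggregate <- function(config, outdir) {
  ins <- require_artifact(outdir, c("predictions.csv", "split.csv",
                                    "world/range_cells.csv"),
                          "aggregate", "train")
  pred <- as.data.frame(data.table::fread(
    file.path(outdir, "predictions.csv")))
  split <- as.data.frame(data.table::fread(file.path(outdir, "split.csv")))
  rc <- data.table::fread(file.path(outdir, "world", "range_cells.csv"))
  range_cells <- split(rc$cell, rc$species_id)
  species <- as.data.frame(data.table::fread(
    file.path(outdir, "world", "species.csv")))
  grid <- grid_spec(config$world$resolution)
  pred <- pred[pred$partition_tag == "all", ]
  dd_ids <- split$species_id[split$role == "dd_holdout"]
  ds_ids <- split$species_id[split$role %in% c("train", "test")]
  pred_dd <- pred[pred$species_id %in% dd_ids, ]
  pred_ds <- pred[pred$species_id %in% ds_ids, ]
  fr <- fraction_dd_threatened(pred_dd, range_cells, grid)
  pc <- percent_change_map(pred_ds, pred_dd, range_cells, grid)
  f1 <- file.path(outdir, "frac_dd_threatened.asc")
  write_asc(fr$frac, grid, f1)
  f2 <- file.path(outdir, "pct_change_pe.asc")
  write_asc(pc$pct_change, grid, f2)
  f3 <- file.path(outdir, "per_class_summary.csv")
  data.table::fwrite(per_class_summary(pred_dd, species), f3)
  list(inputs = ins, outputs = c(f1, f2, f3))
}
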