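#!/usr/bin/env Rscript
# Stage 5 — train the stacked super-learner and score all species.
#
# Partition 1 trains on all training species; partition 2 trains separate
# marine and non-marine models. Each model: 10-fold CV out-of-fold scores
# for the four base learners (L1 GLM, random forest, gradient boosted
# trees, extremely randomized trees) with minority oversampling inside
# each training fold, a non-negative lasso logistic meta-learner on the
# out-of-fold matrix, and an F1-optimal decision threshold. Every
# retained species receives a PE score.

source("analysis/00_common.R")
run <- analysis_setup()

run_stage("train", run$config, run$outdir)

info <- jsonlite::fromJSON(file.path(run$outdir, "model_info.json"))
cat("\npartitions trained:", paste(info$partitions, collapse = ", "), "\n")
cat("meta-learner coefficients (partition 1):\n")
print(unlist(info$meta_coefficients$all))
cat(sprintf("decision threshold (partition 1): %.3f\n",
            info$thresholds$all))
pred <- read.csv(file.path(run$outdir, "predictions.csv"))
cat(sprintf("predictions written for %d species x %d partition tag(s)\n",
            length(unique(pred$species_id)),
            length(unique(pred$partition_tag))))
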