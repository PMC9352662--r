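#!/usr/bin/env Rscript
# Stage 6 — evaluate the classifier.
#
# Test-set confusion-matrix metrics, AUC / AUC_PR / Gini, permutation
# variable importance (AUC loss over 50 permutations per feature), the
# partition choice by mean per-class AUC, and validation on a revealed
# subset of formerly Data Deficient species.

source("analysis/00_common.R")
run <- analysis_setup()

run_stage("evaluate", run$config, run$outdir)

met <- read.csv(file.path(run$outdir, "metrics.csv"))
cat("\ntest-set performance (partition 1):\n")
print(transform(met, value = round(value, 3))[c("metric", "value")],
      row.names = FALSE)
imp <- read.csv(file.path(run$outdir, "importance.csv"))
cat("\ntop 8 features by permutation importance (AUC loss):\n")
print(head(transform(imp, importance = round(importance, 4)), 8),
      row.names = FALSE)
choice <- jsonlite::fromJSON(file.path(run$outdir,
                                       "partition_choice.json"))
cat(sprintf("\npartition selected by mean per-class AUC: %s\n",
            choice$chosen))
rv <- jsonlite::fromJSON(file.path(run$outdir,
                                   "reassessed_validation.json"))
cat(sprintf("formerly-DD validation: %d of %d correct (%.0f%%)\n",
            rv$n_correct, rv$n, 100 * rv$n_correct / rv$n))
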