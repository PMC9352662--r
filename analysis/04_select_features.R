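#!/usr/bin/env Rscript
# Stage 4 — shadow-feature relevance filtering on the training data.
#
# Every predictor competes against permuted copies of all predictors over
# 50 randomized-forest runs; features whose hit counts beat the binomial
# null at the 99% level are confirmed and carried into the classifier.

source("analysis/00_common.R")
run <- analysis_setup()

run_stage("select", run$config, run$outdir)

sel <- read.csv(file.path(run$outdir, "selection.csv"))
conf <- read.csv(file.path(run$outdir, "selection_confirmed.csv"))
cat(sprintf("\n%d of %d feature columns confirmed (%d rejected, %d tentative)\n",
            sum(sel$decision == "confirmed"), nrow(sel),
            sum(sel$decision == "rejected"),
            sum(sel$decision == "tentative")))
cat(sprintf("columns carried into the model (incl. confirmed blocks): %d\n",
            nrow(conf)))
cat("top confirmed columns by hits:\n")
print(head(sel[order(-sel$hits), ], 10), row.names = FALSE)
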