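#!/usr/bin/env Rscript
# Stage 2 — extract the species x predictor feature table.
#
# For every retained species (EX/EW excluded): taxonomy, environmental
# domains, habitat counts, native-country count, range extent (cells and
# km2), occurrence point/cell counts, count-layer sums within the range,
# and min/max/mean/median of every stressor layer over both the range
# cells and the occurrence cells. Occurrence-derived columns stay missing
# (not zero) for species without occurrence records.

source("analysis/00_common.R")
run <- analysis_setup()

run_stage("extract", run$config, run$outdir)

feats <- read.csv(file.path(run$outdir, "features.csv"))
num <- vapply(feats, is.numeric, logical(1))
cat(sprintf("\nfeature table: %d species x %d columns (%d numeric)\n",
            nrow(feats), ncol(feats), sum(num)))
cat(sprintf("missing numeric entries: %.2f%% (imputed downstream)\n",
            100 * mean(is.na(as.matrix(feats[num])))))
cat(sprintf("species without occurrences: %d\n",
            sum(feats$n_occurrence_points == 0)))
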