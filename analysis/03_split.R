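#!/usr/bin/env Rscript
# Stage 3 — exclusion rules and the stratified 75/25 split.
#
# Outdated assessments are dropped (unless a taxonomic class would fall
# below five records), Data Deficient species are set aside as the
# prediction population, and the remaining labelled species are split
# 75/25 into training and testing, preserving the threatened share within
# each family x marine-domain stratum.

source("analysis/00_common.R")
run <- analysis_setup()

run_stage("split", run$config, run$outdir)

split <- read.csv(file.path(run$outdir, "split.csv"))
cat("\nrole assignment:\n")
print(table(split$role))
lab <- split$label[split$role %in% c("train", "test")]
cat(sprintf("labelled species: %d (%.1f%% threatened)\n", length(lab),
            100 * mean(lab == "threatened")))
cat(sprintf("train fraction among labelled: %.3f\n",
            sum(split$role == "train") /
              sum(split$role %in% c("train", "test"))))
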