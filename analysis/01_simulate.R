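#!/usr/bin/env Rscript
# Stage 1 — simulate the synthetic world.
#
# Builds the global 0.5-degree grid, the stressor layers (3 spatially
# autocorrelated causal layers, 20 white-noise layers, 2 count-like
# layers), 2000 species with elliptical range maps, occurrence points,
# taxonomy, and Red List categories drawn from the known logistic threat
# model. Everything is written as plain-text GIS formats under
# <outdir>/world/.

source("analysis/00_common.R")
run <- analysis_setup()

run_stage("simulate", run$config, run$outdir)

species <- read.csv(file.path(run$outdir, "world", "species.csv"))
cat(sprintf("\n%d species generated (seed %d)\n", nrow(species),
            run$config$seed))
cat("Red List categories:\n")
print(table(species$category))
cat(sprintf("true threatened fraction: %.3f (mean model probability %.3f)\n",
            mean(species$true_threatened),
            mean(species$true_probability)))
cat(sprintf("marine species: %.1f%%\n", 100 * mean(species$marine)))
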