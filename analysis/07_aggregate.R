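#!/usr/bin/env Rscript
# Stage 7 — spatial conservation-priority aggregation.
#
# Per grid cell: the fraction of Data Deficient species predicted
# threatened (masked where no DD species occur) and the percent change in
# mean PE score when DD species are pooled with data-sufficient species;
# plus a per-taxonomic-class summary of the DD predictions.

source("analysis/00_common.R")
run <- analysis_setup()

run_stage("aggregate", run$config, run$outdir)

fr <- read_asc(file.path(run$outdir, "frac_dd_threatened.asc"))
pc <- read_asc(file.path(run$outdir, "pct_change_pe.asc"))
cat(sprintf("\nfraction-threatened map: %d cells with DD species; mean %.3f\n",
            sum(!is.na(fr$values)), mean(fr$values, na.rm = TRUE)))
cat(sprintf("percent-change map: %d unmasked cells; mean %+.1f%%, IQR [%+.1f%%, %+.1f%%]\n",
            sum(!is.na(pc$values)), mean(pc$values, na.rm = TRUE),
            stats::quantile(pc$values, 0.25, na.rm = TRUE),
            stats::quantile(pc$values, 0.75, na.rm = TRUE)))
cat("\nper-class summary of DD predictions:\n")
print(read.csv(file.path(run$outdir, "per_class_summary.csv")),
      row.names = FALSE, digits = 3)
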