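# Shared setup for the analysis drivers: load the package, read the study
# configuration, resolve --seed / --outdir overrides.

suppressMessages({
  library(optparse)
  library(perisk)
})

analysis_setup <- function() {
  opts <- parse_args(OptionParser(option_list = list(
    make_option("--config", type = "character",
                default = "analysis/config.yaml"),
    make_option("--seed", type = "integer", default = NA_integer_),
    make_option("--outdir", type = "character", default = "results/run")
  )))
  cfg <- if (file.exists(opts$config)) load_config(opts$config) else
    default_config()
  if (!is.na(opts$seed)) cfg$seed <- opts$seed
  dir.create(opts$outdir, recursive = TRUE, showWarnings = FALSE)
  list(config = cfg, outdir = opts$outdir)
}
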