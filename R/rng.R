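# Seed fan-out: one global seed deterministically derives an independent
# substream seed per pipeline stage / operation, so that changing one
# stage's internals never perturbs another stage's draws.

#' Derive a stage-specific seed from a global seed
#'
#' A small deterministic integer hash combining the global seed with a
#' stage label. Always returns a value in `[1, 2^31 - 2]`, safe for
#' `set.seed()` on any platform.
#'
#' @param seed Integer global seed.
#' @param label Character stage label, e.g. `"features"`.
#' @return Integer derived seed.
#' @export
stage_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483629  # large prime < 2^31
  h <- as.numeric(seed) %% m
  for (c in utf8ToInt(label)) h <- (h * 131 + c) %% m
  h <- (h * 69069 + 1) %% m
  as.integer(h %% (2^31 - 3) + 1)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
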