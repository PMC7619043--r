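## Run code under a fixed RNG seed, restoring the caller's RNG state.
## seed = NULL leaves the RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Deterministic fan-out of a master seed into stage-specific seeds.
## Keeps results below .Machine$integer.max for 32-bit R integers.
stage_seed <- function(master_seed, stage_index) {
  as.integer((as.numeric(master_seed) * 1009 + stage_index * 9973) %% 2147483647)
}
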