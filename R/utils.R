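## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
## All stochastic operations in the package route their randomness through
## this helper so that a seed argument fully determines the output.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a stream of child seeds from a base seed, keeping values inside
## the 32-bit integer range.
child_seeds <- function(seed, k) {
  (as.integer(seed) + 1000003 * seq_len(k)) %% .Machine$integer.max
}
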