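# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. All stochastic draws in the package go through this, so
# a master seed makes every experiment bit-reproducible.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Derive `n` independent sub-seeds from a master seed (all below 2^31).
derive_seeds <- function(master, n) {
  with_seed(master, sample.int(2147483646L, n, replace = FALSE))
}
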