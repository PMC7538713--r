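## Internal helpers shared across modules.

# Run `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards so package functions never perturb user code.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

# Next power of two >= n.
nextPow2 <- function(n) 2^ceiling(log2(n))

stopIfNot <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
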