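# Internal numerical helpers shared across modules.

# log(1 + exp(z)) without overflow for large |z|
softplus <- function(z) pmax(z, 0) + log1p(exp(-abs(z)))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_preserved_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# Pre-draw independent child seeds so replicates can run in any order
# (or concurrently) and still reproduce the sequential result.
child_seeds <- function(seed, n) {
  with_preserved_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
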