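# Deterministic sub-seed derivation and scoped RNG.
#
# Every stochastic stage draws under its own sub-seed derived from the master
# seed, so stages can be replayed independently (e.g. the per-cell Poisson LD
# counts of a rendered field) and adding a stage never perturbs another
# stage's stream. Global RNG state is saved and restored around each draw.

# Derive a reproducible 31-bit sub-seed from (seed, stage index).
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  # splitmix-style mix kept in double precision; exact below 2^53
  x <- (abs(seed) %% 2147483647) + 1
  x <- (x * 48271) %% 2147483647
  x <- (x + stage * 1664525) %% 2147483647
  x <- (x * 69621) %% 2147483647
  as.integer(x)
}

# Evaluate expr with a locally-set RNG seed; global state untouched.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}
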