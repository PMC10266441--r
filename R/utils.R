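# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards.  All stochastic operations in the package go
# through this so that results are reproducible from user-supplied seeds.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a stream of per-step seeds from one master seed.  Kept below
# .Machine$integer.max so they remain valid R seeds.
derive_seeds <- function(master_seed, n, stream = 1L) {
  with_seed(as.integer(master_seed) + 97L * as.integer(stream), {
    sample.int(.Machine$integer.max - 1L, n, replace = FALSE)
  })
}

is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

stop_rxn <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "rxnbo_error")
}
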