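# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All exported generators funnel their
# randomness through this so that a given seed is reproducible regardless of
# surrounding RNG use.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed %% 2147483647L))
  }
  expr
}

# Deterministic sub-seed derivation: mixes a base seed with an index so that
# per-subject / per-sequence streams are independent but reproducible.
derive_seed <- function(base, index) {
  as.integer((as.numeric(base) * 7919 + as.numeric(index) * 104729) %% 2147483647)
}

# ms -> 1-based sample index at a given sampling rate
ms_to_sample <- function(ms, rate) as.integer(round(ms * rate / 1000)) + 1L

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
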