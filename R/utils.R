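# internal helpers shared across modules

# Evaluate `expr` with the RNG temporarily seeded; restores the caller's
# RNG state so simulations don't perturb the global stream.  seed = NULL
# runs under the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and an index, staying inside the
# 32-bit integer range R's set.seed() accepts.
child_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 1009 + 7919 * as.double(i)) %% 2147483647)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

stop_critpow <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
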