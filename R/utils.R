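#' @keywords internal
"_PACKAGE"

# Deterministic sub-seed for a named stage, derived from one root seed.
# Keeps every random draw in the package on named substreams of a single
# root seed (kept below 2^31 - 1 so it is always a valid R integer).
substream_seed <- function(root_seed, name) {
  stopifnot(is.numeric(root_seed), length(root_seed) == 1L)
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((abs(root_seed) * 7919 + h * 104729) %% 2147483563) + 1L
}

# Evaluate `expr` under a given seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Numerically stable log(1 + exp(x)).
log1pexp <- function(x) {
  out <- x
  small <- x <= 18
  out[small] <- log1p(exp(x[small]))
  big <- x > 18 & x <= 33.3
  out[big] <- x[big] + exp(-x[big])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
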