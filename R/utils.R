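# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's .Random.seed is restored afterwards. seed = NULL leaves the
# global RNG stream untouched (and advances it).
with_rng_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number or NULL.")
  }
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a child seed from a root seed for a named stage, keeping the
# result inside the 32-bit integer range.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) + 1009L * as.integer(offset)) %% 2147483587L
}

# Population variance (divide by N, not N - 1).
pop_var <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  mean((x - mean(x))^2)
}

# Off-diagonal entries of a square matrix as a plain vector.
off_diagonal <- function(m) {
  m <- as.matrix(m)
  m[row(m) != col(m)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
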