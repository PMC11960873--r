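#' Derive a stream-specific seed from a master seed
#'
#' Splitmix-style integer mixing so that every pipeline stage (synthesis,
#' fold shuffling, weight initialization, dropout, ...) draws from an
#' independent, reproducible stream. The result always fits in a 32-bit
#' signed integer, as required by [set.seed()].
#'
#' @param seed master seed (integer)
#' @param stream integer stream label (>= 0)
#' @return an integer seed in `[0, 2^31 - 2]`
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), is.numeric(stream), length(seed) == 1L)
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  s <- (abs(seed) %% m) + 1
  # two multiplicative mixing rounds; constants from Park-Miller / Knuth
  s <- (s * 48271) %% m
  s <- (s + (stream %% m) * 69621) %% m
  s <- (s * 16807) %% m
  as.integer(s)
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

softmax_cols <- function(z) {
  z <- sweep(z, 2L, apply(z, 2L, max), "-")
  e <- exp(z)
  sweep(e, 2L, colSums(e), "/")
}

# Moore-Penrose pseudo-inverse via SVD (used to lift mel-plane masks to the
# linear-frequency STFT plane).
pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * s$d[1L]
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
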