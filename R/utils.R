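# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

#' Circular distance between bins
#'
#' Genomic separation on a circular genome of `n` bins:
#' `d(i, j) = min(|i - j|, n - |i - j|)`. Indices are 1-based.
#'
#' @param i,j Bin indices (vectors recycle).
#' @param n Number of bins on the circle.
#' @return Integer vector of circular bin distances.
#' @export
circular_distance <- function(i, j, n) {
  d <- abs(i - j)
  pmin(d, n - d)
}

# Distance matrix of circular bin separations for an n-bin genome.
circular_distance_matrix <- function(n) {
  idx <- seq_len(n)
  outer(idx, idx, circular_distance, n = n)
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  }
  invisible(x)
}

# Sample skewness and excess kurtosis (moment estimators).
moment_skewness <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x); s <- stats::sd(x)
  if (s == 0) return(0)
  mean((x - m)^3) / s^3
}

moment_kurtosis <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x); s <- stats::sd(x)
  if (s == 0) return(0)
  mean((x - m)^4) / s^4 - 3
}
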