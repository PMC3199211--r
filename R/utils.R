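# Internal numeric helpers shared across modules.

#' @keywords internal
#' @noRd
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise log-sum-exp of a matrix.
#' @noRd
row_logsumexp <- function(X) {
  m <- apply(X, 1L, max)
  m + log(rowSums(exp(X - m)))
}

# Reflect an integer index into 1..n (symmetric reflection with edge
# repetition, scipy-style "reflect"/MATLAB "symmetric"): for n = 4 the
# extension reads ... b a | a b c d | d c ...  Works for arbitrarily
# far out-of-range indices (kernels wider than the image fold repeatedly).
#' @noRd
reflect_index <- function(idx, n) {
  if (n == 1L) return(rep(1L, length(idx)))
  period <- 2L * n
  j <- (idx - 1L) %% period        # 0-based position in one period
  ifelse(j < n, j + 1L, period - j)
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Convert between a length-N_P row-major pixel vector and an H x W matrix.
# Pixel i corresponds to row floor((i-1)/W)+1, column ((i-1) %% W)+1.
#' @noRd
field_to_matrix <- function(v, height, width) {
  matrix(v, nrow = height, ncol = width, byrow = TRUE)
}

#' @noRd
matrix_to_field <- function(M) as.vector(t(M))

# Log-density of a multivariate normal; x is n x d, mu length d,
# sigma d x d symmetric positive definite.
#' @noRd
mvn_logpdf <- function(x, mu, sigma) {
  x <- as.matrix(x)
  d <- ncol(x)
  R <- chol(sigma)
  z <- backsolve(R, t(x) - mu, transpose = TRUE)   # R^T z = (x - mu)^T
  -0.5 * colSums(z^2) - sum(log(diag(R))) - 0.5 * d * log(2 * pi)
}
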