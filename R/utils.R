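#' Arcsinh intensity transform
#'
#' The working scale for fluorescence intensities: `asinh(x / cofactor)`.
#' `asinh_inverse()` maps transformed values back to the raw scale.
#'
#' @param x Numeric vector.
#' @param cofactor Positive scale divisor; 150 is the conventional choice for
#'   photomultiplier-based cytometers.
#' @return Numeric vector of the same length.
#' @examples
#' asinh_transform(150, cofactor = 150) # asinh(1) = log(1 + sqrt(2))
#' @export
asinh_transform <- function(x, cofactor = 150) {
  if (!is.numeric(cofactor) || length(cofactor) != 1 || cofactor <= 0) {
    abort("`cofactor` must be a single positive number")
  }
  asinh(x / cofactor)
}

#' @rdname asinh_transform
#' @export
asinh_inverse <- function(x, cofactor = 150) {
  if (cofactor <= 0) abort("`cofactor` must be positive")
  sinh(x) * cofactor
}

# Deterministic child seeds below 2^31, derived from a master seed without
# disturbing the caller's RNG stream.
derive_seeds <- function(master_seed, n) {
  withr::with_seed(as.integer(master_seed),
                   sample.int(.Machine$integer.max - 1L, n))
}

#' Validate a correlation matrix for copula use
#'
#' Checks squareness, symmetry, unit diagonal, entries in `[-1, 1]` and
#' positive semi-definiteness (within `tol`); errors with a diagnostic
#' otherwise.
#'
#' @param R Numeric matrix.
#' @param tol Numerical tolerance for symmetry and the smallest eigenvalue.
#' @return `R`, invisibly.
#' @export
check_correlation_matrix <- function(R, tol = 1e-8) {
  if (!is.matrix(R) || nrow(R) != ncol(R)) {
    abort("correlation matrix must be square")
  }
  if (max(abs(R - t(R))) > tol) abort("correlation matrix must be symmetric")
  if (max(abs(diag(R) - 1)) > tol) {
    abort("correlation matrix must have unit diagonal")
  }
  if (any(R < -1 - tol | R > 1 + tol)) {
    abort("correlation entries must lie in [-1, 1]")
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol) {
    abort(sprintf(
      "correlation matrix is not positive semi-definite (min eigenvalue %.3g)",
      min(ev)))
  }
  invisible(R)
}

# Draw n rows from a multivariate normal with given means, sds and correlation
# matrix (Cholesky with a tiny jitter fallback for semi-definite inputs).
rmvn_correlated <- function(n, mu, sigma, R) {
  d <- length(mu)
  Z <- matrix(rnorm(n * d), nrow = n, ncol = d)
  L <- tryCatch(chol(R), error = function(e) chol(R + diag(1e-10, d)))
  X <- Z %*% L
  sweep(sweep(X, 2, sigma, `*`), 2, mu, `+`)
}

`%||%` <- rlang::`%||%`
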