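#' Singular-value soft-thresholding
#'
#' The proximal operator of the nuclear norm, `D_tau`: compute an SVD
#' `M = U diag(s) V'` and soft-threshold the singular values,
#' `svt(M, tau) = U diag(max(s - tau, 0)) V'`. This is the unique minimizer of
#' `tau * ||Y||_* + 0.5 * ||Y - M||_F^2`.
#'
#' Singular values below `1e-12` after thresholding are treated as exactly
#' zero, which stabilizes the rank of the result.
#'
#' @param M numeric matrix with finite entries.
#' @param tau nonnegative threshold.
#' @return matrix of the same dimensions as `M`.
#' @seealso [shrink()] for the elementwise L1 counterpart.
#' @export
#' @examples
#' svt(diag(c(3, 1)), 2)  # diag(1, 0)
svt <- function(M, tau) {
  M <- as.matrix(M)
  check_finite(M, "M")
  check_scalar(tau, "tau", lower = 0)
  sv <- svd(M)
  d <- pmax(sv$d - tau, 0)
  keep <- d > 1e-12
  if (!any(keep)) {
    return(matrix(0, nrow(M), ncol(M)))
  }
  sv$u[, keep, drop = FALSE] %*% (d[keep] * t(sv$v[, keep, drop = FALSE]))
}

#' Elementwise shrinkage (soft-thresholding)
#'
#' The proximal operator of the elementwise L1 norm, `S_tau`: each entry `m`
#' maps to `sign(m) * max(|m| - tau, 0)`.
#'
#' @param M numeric matrix or vector.
#' @param tau nonnegative threshold.
#' @return object of the same shape as `M`.
#' @export
#' @examples
#' shrink(c(-3, 0.5), 1)  # -2, 0
shrink <- function(M, tau) {
  check_finite(M, "M")
  check_scalar(tau, "tau", lower = 0)
  sign(M) * pmax(abs(M) - tau, 0)
}
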