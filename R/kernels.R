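#' Kernel specification
#'
#' Describes the kernel used on the frame columns of the motion matrix for the
#' kernelized low-rank representation term. `rbf` is the Gaussian kernel
#' `exp(-||x_i - x_j||^2 / (2 sigma^2))`; `linear` gives `K = X'X`, recovering
#' the linear LRR behaviour as a degenerate case.
#'
#' @param kind `"rbf"` or `"linear"`.
#' @param bandwidth positive numeric sigma, or `"median"` for the
#'   median-pairwise-distance heuristic (resolved against the data before use).
#' @param median_scale multiplier applied to the median distance when the
#'   heuristic is used; bandwidths below the raw median sharpen the kernel's
#'   distinction between nearby and distant frames.
#' @return object of class `kernel_spec`.
#' @export
kernel_spec <- function(kind = c("rbf", "linear"), bandwidth = "median",
                        median_scale = 0.5) {
  kind <- match.arg(kind)
  if (is.character(bandwidth)) {
    if (!identical(bandwidth, "median")) {
      stop_input("'bandwidth' must be a positive number or \"median\"")
    }
  } else {
    check_scalar(bandwidth, "bandwidth")
    if (bandwidth <= 0) stop_input("'bandwidth' must be > 0")
  }
  check_scalar(median_scale, "median_scale")
  if (median_scale <= 0) stop_input("'median_scale' must be > 0")
  structure(list(kind = kind, bandwidth = bandwidth,
                 median_scale = median_scale),
            class = "kernel_spec")
}

#' Median-heuristic bandwidth
#'
#' Median of the pairwise Euclidean distances between frame columns of `X`.
#' Falls back to 1 with a warning when the median distance is zero (all
#' frames identical).
#'
#' @param X motion matrix, 3NP x NF.
#' @return positive bandwidth.
#' @export
median_bandwidth <- function(X) {
  d <- stats::median(stats::dist(t(X)))
  if (!is.finite(d) || d <= 0) {
    warning("median pairwise distance is zero; falling back to bandwidth 1", call. = FALSE)
    return(1)
  }
  d
}

# replace "median" by a numeric value computed on X
resolve_bandwidth <- function(spec, X) {
  if (spec$kind == "rbf" && is.character(spec$bandwidth)) {
    spec$bandwidth <- (spec$median_scale %||% 1) * median_bandwidth(X)
  }
  spec
}

#' Kernel matrix on frame columns
#'
#' `K_ij = k(x_i, x_j)` for the columns `x_i` of the motion matrix, so `K` is
#' NF x NF, symmetric and positive semi-definite; the rbf kernel has unit
#' diagonal.
#'
#' @param X motion matrix, 3NP x NF.
#' @param spec a [kernel_spec()]. A `"median"` bandwidth is resolved on `X`.
#' @return NF x NF kernel matrix.
#' @export
kernel_matrix <- function(X, spec = kernel_spec()) {
  X <- as.matrix(X)
  check_finite(X, "X")
  if (spec$kind == "linear") {
    K <- crossprod(X)
    return((K + t(K)) / 2)
  }
  spec <- resolve_bandwidth(spec, X)
  G <- crossprod(X)
  sq <- diag(G)
  D2 <- pmax(outer(sq, sq, "+") - 2 * G, 0)
  K <- exp(-D2 / (2 * spec$bandwidth^2))
  K <- (K + t(K)) / 2
  diag(K) <- 1
  K
}

#' Kernel regularization value
#'
#' Evaluates `trace(C' K C)`, the kernelized low-rank representation penalty
#' at `C = I - Z`. Nonnegative whenever `K` is positive semi-definite.
#'
#' @param K NF x NF kernel matrix.
#' @param C NF x NF matrix.
#' @return scalar value.
#' @export
kernel_term_value <- function(K, C) {
  if (!is.matrix(K) || !is.matrix(C) || any(dim(K) != dim(C)) || nrow(K) != ncol(K)) {
    stop_input("'K' and 'C' must be square matrices of the same size")
  }
  sum(C * (K %*% C))
}

#' Gradient of the kernel term with respect to the motion matrix
#'
#' Gradient of `trace(C' K(X) C)` in `X`, including the dependence of the
#' kernel matrix on `X`. Writing `M = C C'` and `A = M * K` (elementwise), the
#' rbf gradient column i is `-(2/sigma^2) * sum_j A_ij (x_i - x_j)`; the
#' linear-kernel gradient is `2 X M`.
#'
#' @param X motion matrix, 3NP x NF.
#' @param C NF x NF matrix.
#' @param spec a [kernel_spec()]; a `"median"` bandwidth is resolved on `X`.
#' @return gradient matrix, same shape as `X`.
#' @export
kernel_term_gradient <- function(X, C, spec = kernel_spec()) {
  X <- as.matrix(X)
  M <- tcrossprod(C)
  if (spec$kind == "linear") {
    return(2 * X %*% M)
  }
  if (spec$kind != "rbf") stop_input("unsupported kernel kind")
  spec <- resolve_bandwidth(spec, X)
  K <- kernel_matrix(X, spec)
  A <- M * K
  s <- rowSums(A)
  -(2 / spec$bandwidth^2) * (sweep(X, 2, s, "*") - X %*% A)
}
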