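#' Scale-normalized mean reconstruction error
#'
#' Computes the relative 3D reconstruction error: per-joint, per-frame
#' Euclidean distances `e_fp` between the estimate and the ground truth,
#' normalized by the ground-truth scale
#' `sigma = (1 / 3NF) sum_f (sigma_fx + sigma_fy + sigma_fz)` (the per-frame
#' coordinate standard deviations of the ground-truth shape), so
#' `e_mean = mean(e_fp) / sigma`. Monocular orthographic reconstruction has a
#' global depth-flip ambiguity; the error is evaluated for the estimate and
#' its depth-reflected copy (z negated for the whole sequence) and the
#' smaller one is reported along with the flip used. The median error uses
#' the same normalization and the midpoint convention for even counts.
#'
#' @param X_est estimated motion matrix, 3NP x NF.
#' @param X_gt ground-truth motion matrix, same shape.
#' @param flip apply sequence-level depth-flip alignment (default `TRUE`).
#' @return object of class `error_report`: `e_mean`, `e_med`, `e_fp` (NF x NP
#'   distance matrix for the chosen flip, unnormalized), `sigma`, `flip_used`
#'   (+1 or -1).
#' @export
emean <- function(X_est, X_gt, flip = TRUE) {
  X_est <- as.matrix(X_est); X_gt <- as.matrix(X_gt)
  if (any(dim(X_est) != dim(X_gt))) stop_input("estimate and ground truth shapes differ")
  d <- motion_dims(X_gt)
  sig <- 0
  for (f in seq_len(d$nf)) {
    S <- matrix(X_gt[, f], 3, d$np)
    sig <- sig + sum(apply(S, 1, stats::sd))
  }
  sig <- sig / (3 * d$nf)
  if (!is.finite(sig) || sig <= 0) {
    stop_input("degenerate ground truth: zero coordinate spread")
  }
  per_point <- function(Xe) {
    Dm <- matrix(0, d$nf, d$np)
    for (p in seq_len(d$np)) {
      Df <- Xe[joint_rows(p), , drop = FALSE] - X_gt[joint_rows(p), , drop = FALSE]
      Dm[, p] <- sqrt(colSums(Df * Df))
    }
    Dm
  }
  e_plus <- per_point(X_est)
  flip_used <- 1
  e_fp <- e_plus
  if (flip) {
    Xf <- X_est
    Xf[seq(3, nrow(Xf), by = 3), ] <- -Xf[seq(3, nrow(Xf), by = 3), ]
    e_minus <- per_point(Xf)
    if (mean(e_minus) < mean(e_plus)) {
      e_fp <- e_minus
      flip_used <- -1
    }
  }
  structure(list(e_mean = mean(e_fp) / sig,
                 e_med = emed(e_fp, sig),
                 e_fp = e_fp, sigma = sig, flip_used = flip_used),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("<error_report: e_mean = %.4f, e_med = %.4f (sigma = %.4g, flip %+d)>\n",
              x$e_mean, x$e_med, x$sigma, x$flip_used))
  invisible(x)
}

#' Scale-normalized median reconstruction error
#'
#' Median over all NF x NP per-point errors, divided by `sigma` (the same
#' ground-truth scale as [emean()]); the midpoint convention is used for
#' even counts.
#'
#' @param e_fp matrix (or vector) of per-point Euclidean errors.
#' @param sigma positive normalization scale.
#' @return scalar.
#' @export
emed <- function(e_fp, sigma = 1) {
  if (length(e_fp) == 0) stop_input("'e_fp' must be non-empty")
  stats::median(as.vector(e_fp)) / sigma
}

#' Spectral clustering of the affinity matrix
#'
#' Symmetrizes the recovered self-expressive coefficients,
#' `A = (|Z| + |Z'|) / 2`, and applies normalized spectral clustering: the
#' top eigenvectors of `D^{-1/2} A D^{-1/2}` are row-normalized and grouped
#' by k-means. Deterministic given `seed`.
#'
#' @param Z NF x NF affinity (self-expressive coefficient) matrix.
#' @param n_clusters number of clusters (`1 <= n_clusters <= NF`).
#' @param seed integer seed for the k-means step.
#' @return integer vector of per-frame labels in `1..n_clusters`.
#' @export
affinity_to_clusters <- function(Z, n_clusters, seed = 1) {
  Z <- as.matrix(Z)
  nf <- nrow(Z)
  if (ncol(Z) != nf) stop_input("'Z' must be square")
  if (n_clusters < 1 || n_clusters > nf) stop_input("'n_clusters' must lie in 1..NF")
  n_clusters <- as.integer(n_clusters)
  if (n_clusters == 1L) return(rep(1L, nf))
  A <- (abs(Z) + abs(t(Z))) / 2
  dgr <- pmax(rowSums(A), .Machine$double.eps)
  Lsym <- A / sqrt(dgr) / rep(sqrt(dgr), each = nf)
  V <- eigen((Lsym + t(Lsym)) / 2, symmetric = TRUE)$vectors[, seq_len(n_clusters), drop = FALSE]
  rn <- sqrt(rowSums(V * V))
  V <- V / pmax(rn, .Machine$double.eps)
  km <- withr::with_seed(seed,
                         stats::kmeans(V, centers = n_clusters, nstart = 100,
                                       iter.max = 100))
  as.integer(km$cluster)
}

#' Temporal consistency of frame labels
#'
#' Fraction of consecutive frame pairs carrying the same cluster label; 1 for
#' a constant labelling, 0 for one that switches at every frame.
#'
#' @param labels integer vector of per-frame labels (length >= 2).
#' @return value in `[0, 1]`.
#' @export
temporal_consistency <- function(labels) {
  n <- length(labels)
  if (n < 2) stop_input("need at least two frames")
  mean(labels[-1] == labels[-n])
}

#' Clustering accuracy up to label permutation
#'
#' Best agreement between predicted and reference labels over all
#' permutations of the predicted label set.
#'
#' @param labels,truth integer label vectors of equal length.
#' @return accuracy in `[0, 1]`.
#' @export
label_accuracy <- function(labels, truth) {
  if (length(labels) != length(truth)) stop_input("label vectors differ in length")
  ul <- sort(unique(labels))
  ut <- sort(unique(truth))
  k <- max(length(ul), length(ut))
  if (k > 8) stop_input("too many clusters for exhaustive permutation matching")
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  targets <- if (length(ut) < length(ul)) c(ut, seq_len(length(ul) - length(ut)) + max(ut)) else ut
  best <- 0
  for (pm in perms(targets)) {
    mapped <- pm[match(labels, ul)]
    best <- max(best, mean(mapped == truth, na.rm = TRUE))
  }
  best
}
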