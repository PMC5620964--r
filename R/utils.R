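# Internal helpers shared across modules.

stop_input <- function(...) stop(..., call. = FALSE)

check_finite <- function(M, name) {
  if (!all(is.finite(M))) stop_input(sprintf("'%s' must have only finite entries", name))
  invisible(M)
}

check_scalar <- function(x, name, lower = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_input(sprintf("'%s' must be a single number", name))
  }
  if (x < lower) stop_input(sprintf("'%s' must be >= %g", name, lower))
  invisible(x)
}

fnorm <- function(M) sqrt(sum(M * M))

# Moore-Penrose pseudo-inverse solve of G b = w with rank reporting.
pinv_solve <- function(G, W, warn = TRUE) {
  sv <- svd(G)
  tol <- max(dim(G)) * .Machine$double.eps * max(sv$d, 0)
  keep <- sv$d > tol
  if (warn && sum(keep) < min(dim(G))) {
    warning("rank-deficient least-squares system; using pseudo-inverse", call. = FALSE)
  }
  if (!any(keep)) return(matrix(0, ncol(G), ncol(W)))
  sv$v[, keep, drop = FALSE] %*%
    ((t(sv$u[, keep, drop = FALSE]) %*% W) / sv$d[keep])
}

# number of frames / points from a 3NP x NF motion matrix
motion_dims <- function(X) {
  if (nrow(X) %% 3L != 0L) stop_input("motion matrix must have 3*NP rows")
  list(np = nrow(X) %/% 3L, nf = ncol(X))
}

joint_rows <- function(p) (3L * (p - 1L) + 1L):(3L * p)
frame_rows2 <- function(f) (2L * (f - 1L) + 1L):(2L * f)
frame_rows3 <- function(f) (3L * (f - 1L) + 1L):(3L * f)
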