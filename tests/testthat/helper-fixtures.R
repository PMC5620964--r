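# Shared fixtures and independent oracles used across the test files.

rand_mat <- function(n, m, seed) {
  withr::with_seed(seed, matrix(rnorm(n * m), n, m))
}

# independent SVT oracle: LAPACK dgesvd route (La.svd) + explicit soft-threshold
svt_oracle <- function(M, tau) {
  sv <- La.svd(M)
  d <- pmax(sv$d - tau, 0)
  sv$u %*% (d * sv$vt)
}

# dense block-diagonal camera matrix R (2NF x 3NF)
blockdiag_cams <- function(cams) {
  nf <- dim(cams)[3]
  R <- matrix(0, 2 * nf, 3 * nf)
  for (f in seq_len(nf)) {
    R[(2 * f - 1):(2 * f), (3 * f - 2):(3 * f)] <- cams[, , f]
  }
  R
}

# reference projection through the dense block-diagonal matrix
project_sharp_ref <- function(cams, Xsharp) {
  blockdiag_cams(cams) %*% Xsharp
}

# central finite-difference gradient of f at x (vectorized over coordinates)
fd_gradient <- function(f, x, h = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h
    xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

rel_err <- function(a, b) {
  max(abs(a - b)) / max(max(abs(b)), 1e-12)
}

# small deterministic scene shared by mid-size tests
small_scene <- function(nf_each = 12, seed = 11) {
  make_scene(actions = c("swing", "crouch"), n_frames = nf_each,
             deg_per_frame = 4, seed = seed)
}

# minimal solver state for subproblem tests
toy_state <- function(np = 3, nf = 5, seed = 42) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(3 * np * nf), 3 * np, nf)
    list(X = X, Xhat = X + 0.1 * matrix(rnorm(3 * np * nf), 3 * np, nf),
         Z = matrix(rnorm(nf^2, sd = 0.1), nf, nf),
         C = matrix(rnorm(nf^2, sd = 0.1), nf, nf),
         E = matrix(0, 2 * nf, np),
         Gamma1 = matrix(rnorm(2 * nf * np, sd = 0.1), 2 * nf, np),
         Gamma2 = matrix(rnorm(nf^2, sd = 0.1), nf, nf),
         Gamma3 = matrix(rnorm(3 * np * nf, sd = 0.1), 3 * np, nf),
         mu = 2, W = matrix(rnorm(2 * nf * np), 2 * nf, np),
         trusted = matrix(TRUE, 2 * nf, np),
         np = np, nf = nf, residuals = NULL)
  })
}
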