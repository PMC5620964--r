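#' Solver hyperparameters
#'
#' Weights and schedule for the ALM reconstruction. The lambda weights apply
#' after the observation matrix is scale-normalized to unit root-mean-square,
#' so their defaults are unitless. `lambda5` is only used in marker-less mode.
#'
#' @param lambda1 weight of the nuclear-norm shape prior on `X`.
#' @param lambda2 weight of the L1 reprojection error `E`.
#' @param lambda3 weight of the kernelized low-rank representation term.
#' @param lambda4 weight of the soft bone-inextensibility residual.
#' @param lambda5 weight of the heightmap data term (marker-less mode).
#' @param mu0,rho,mu_max penalty schedule: `mu <- min(rho * mu, mu_max)` each
#'   iteration, starting at `mu0` (`rho > 1`).
#' @param tol convergence tolerance on the largest normalized constraint
#'   residual.
#' @param max_iter maximum number of outer ALM iterations.
#' @param inner_iter bound on L-BFGS iterations for the `X` subproblem.
#' @param n_basis number of DCT trajectory basis vectors for initialization;
#'   `NULL` picks `max(2, ceiling(0.1 * NF))`.
#' @param kernel a [kernel_spec()].
#' @param center_tracks subtract the per-frame 2D centroid from the tracks
#'   before solving (removes unknown image translation; disable for inputs
#'   that are already translation-free).
#' @param seed integer seed for any randomized post-processing (e.g. spectral
#'   clustering of the affinity).
#' @param verbose print progress every 50 iterations.
#' @return object of class `tuns_params`.
#' @export
tuns_params <- function(lambda1 = 0.02, lambda2 = 10, lambda3 = 5, lambda4 = 1,
                        lambda5 = 1, mu0 = 1e-3, rho = 1.1, mu_max = 1e8,
                        tol = 1e-6, max_iter = 300, inner_iter = 20,
                        n_basis = NULL, kernel = kernel_spec(),
                        center_tracks = TRUE, seed = 1L, verbose = FALSE) {
  p <- list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
            lambda4 = lambda4, lambda5 = lambda5, mu0 = mu0, rho = rho,
            mu_max = mu_max, tol = tol, max_iter = as.integer(max_iter),
            inner_iter = as.integer(inner_iter), n_basis = n_basis,
            kernel = kernel, center_tracks = isTRUE(center_tracks),
            seed = as.integer(seed), verbose = isTRUE(verbose))
  errs <- validate_params(p)
  if (length(errs)) stop_input(paste(errs, collapse = "; "))
  structure(p, class = "tuns_params")
}

validate_params <- function(p) {
  errs <- character()
  for (nm in paste0("lambda", 1:5)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || is.na(p[[nm]]) || p[[nm]] < 0) {
      errs <- c(errs, sprintf("'%s' must be a nonnegative number", nm))
    }
  }
  if (!is.numeric(p$mu0) || p$mu0 <= 0) errs <- c(errs, "'mu0' must be > 0")
  if (!is.numeric(p$rho) || p$rho <= 1) errs <- c(errs, "'rho' must be > 1")
  if (!is.numeric(p$mu_max) || p$mu_max <= p$mu0) errs <- c(errs, "'mu_max' must exceed 'mu0'")
  if (!is.numeric(p$tol) || p$tol <= 0) errs <- c(errs, "'tol' must be > 0")
  if (is.na(p$max_iter) || p$max_iter < 1) errs <- c(errs, "'max_iter' must be >= 1")
  if (is.na(p$inner_iter) || p$inner_iter < 1) errs <- c(errs, "'inner_iter' must be >= 1")
  if (!is.null(p$n_basis) && (!is.numeric(p$n_basis) || p$n_basis < 1)) {
    errs <- c(errs, "'n_basis' must be >= 1 or NULL")
  }
  if (!inherits(p$kernel, "kernel_spec")) errs <- c(errs, "'kernel' must be a kernel_spec")
  errs
}

# orthonormal DCT-II basis, NF x n
dct_basis <- function(nf, n) {
  f <- seq_len(nf)
  D <- sapply(seq_len(n), function(k) {
    sqrt(2 / nf) * cos(pi * (2 * f - 1) * (k - 1) / (2 * nf))
  })
  D <- matrix(D, nf, n)
  D[, 1] <- D[, 1] / sqrt(2)
  D
}

#' DCT trajectory initialization
#'
#' Point-trajectory style initializer: with rotations known, the 3D trajectory
#' of each joint is constrained to the span of the first `n_basis` DCT basis
#' vectors over frames and fitted to the observations by linear least squares,
#' `min ||W - R X#||_F^2`. Rank-deficient systems (always the case for small
#' camera motion, where depth is unobservable) are resolved by the minimum-norm
#' pseudo-inverse solution with a warning.
#'
#' @param W observation matrix, 2NF x NP.
#' @param cams a [camera_track()].
#' @param n_basis number of DCT basis vectors, `1 <= n_basis <= NF`.
#' @param damping relative Tikhonov damping of the singular values
#'   (`sigma / (sigma^2 + (damping * sigma_max)^2)`); bounds the coefficient
#'   amplification along weakly observed trajectory directions. `0` gives the
#'   exact minimum-norm least-squares solution.
#' @return motion matrix X, 3NP x NF.
#' @export
init_trajectory_dct <- function(W, cams, n_basis, damping = 1e-2) {
  nf <- n_frames(cams)
  np <- ncol(W)
  if (nrow(W) != 2 * nf) stop_input("'W' must have 2*NF rows")
  if (n_basis < 1 || n_basis > nf) stop_input("'n_basis' must lie in 1..NF")
  n_basis <- as.integer(n_basis)
  D <- dct_basis(nf, n_basis)
  # Rstack: 2NF x 3 (frame f occupies rows 2f-1, 2f)
  Rstack <- matrix(aperm(unclass(cams), c(1, 3, 2)), nrow = 2 * nf, ncol = 3)
  G <- matrix(0, 2 * nf, 3 * n_basis)
  for (k in seq_len(n_basis)) {
    G[, (3 * k - 2):(3 * k)] <- Rstack * rep(D[, k], each = 2)
  }
  B <- if (damping > 0) {
    sv <- svd(G)
    eps <- damping * max(sv$d)
    sv$v %*% ((sv$d / (sv$d^2 + eps^2)) * (t(sv$u) %*% W))
  } else {
    pinv_solve(G, W)                          # 3 n_basis x NP
  }
  arrB <- array(B, dim = c(3, n_basis, np))
  Xs <- array(0, dim = c(3, nf, np))
  for (a in 1:3) {
    Xs[a, , ] <- D %*% matrix(arrB[a, , ], n_basis, np)
  }
  to_pointwise(matrix(Xs, 3 * nf, np))
}

# per-joint damped least-squares trajectory fit with untrusted observation
# rows excluded from the design (used by the robust initialization)
masked_trajectory_dct <- function(W, cams, n_basis, trusted, damping = 1e-2) {
  nf <- n_frames(cams)
  np <- ncol(W)
  D <- dct_basis(nf, n_basis)
  Rstack <- matrix(aperm(unclass(cams), c(1, 3, 2)), nrow = 2 * nf, ncol = 3)
  G <- matrix(0, 2 * nf, 3 * n_basis)
  for (k in seq_len(n_basis)) {
    G[, (3 * k - 2):(3 * k)] <- Rstack * rep(D[, k], each = 2)
  }
  eps <- damping * svd(G, nu = 0, nv = 0)$d[1]
  B <- matrix(0, 3 * n_basis, np)
  I <- diag(3 * n_basis)
  for (p in seq_len(np)) {
    rows <- which(trusted[, p])
    Gm <- G[rows, , drop = FALSE]
    B[, p] <- solve(crossprod(Gm) + eps^2 * I, crossprod(Gm, W[rows, p]))
  }
  arrB <- array(B, dim = c(3, n_basis, np))
  Xs <- array(0, dim = c(3, nf, np))
  for (a in 1:3) {
    Xs[a, , ] <- D %*% matrix(arrB[a, , ], n_basis, np)
  }
  to_pointwise(matrix(Xs, 3 * nf, np))
}

#' ALM subproblem updates
#'
#' Closed-form updates of the ALM blocks. `update_Z` and `update_Xhat` are
#' singular-value thresholding steps, `update_E` is elementwise shrinkage of
#' the reprojection residual, and `update_C` solves the linear system
#' `(2 lambda3 K + mu I) C = mu (I - Z) - Gamma2`.
#'
#' @param C,Z,K,E NF x NF (or 2NF x NP for `E`) current blocks.
#' @param Gamma1,Gamma2,Gamma3 Lagrange multiplier matrices.
#' @param mu positive penalty parameter.
#' @param lambda1,lambda2,lambda3 objective weights.
#' @param X,Xsharp current motion matrix (pointwise / framewise layout).
#' @param W observation matrix.
#' @param cams a [camera_track()].
#' @name alm_updates
NULL

#' @rdname alm_updates
#' @export
update_Z <- function(C, Gamma2, mu) {
  check_scalar(mu, "mu")
  if (mu <= 0) stop_input("'mu' must be > 0")
  svt(diag(nrow(C)) - C - Gamma2 / mu, 1 / mu)
}

#' @rdname alm_updates
#' @export
update_Xhat <- function(X, Gamma3, mu, lambda1) {
  check_scalar(mu, "mu")
  if (mu <= 0) stop_input("'mu' must be > 0")
  svt(X + Gamma3 / mu, lambda1 / mu)
}

#' @rdname alm_updates
#' @export
update_E <- function(W, Xsharp, Gamma1, mu, lambda2, cams) {
  if (mu <= 0) stop_input("'mu' must be > 0")
  shrink(W - project_sharp(cams, Xsharp) + Gamma1 / mu, lambda2 / mu)
}

#' @rdname alm_updates
#' @export
update_C <- function(K, Z, Gamma2, mu, lambda3) {
  if (mu <= 0) stop_input("'mu' must be > 0")
  nf <- nrow(K)
  A <- 2 * lambda3 * K + mu * diag(nf)
  rhs <- mu * (diag(nf) - Z) - Gamma2
  tryCatch(solve(A, rhs), error = function(e) {
    warning("ill-conditioned C system; solving by pseudo-inverse", call. = FALSE)
    MASS::ginv(A) %*% rhs
  })
}

# objective and gradient of the X subproblem (all terms that depend on X)
x_subproblem <- function(state, hyper, cams, skel, spec) {
  np <- state$np; nf <- state$nf
  anchor <- state$Xhat - state$Gamma3 / state$mu
  target <- state$W - state$E + state$Gamma1 / state$mu
  list(
    fn = function(xvec) {
      X <- matrix(xvec, 3 * np, nf)
      val <- 0
      if (hyper$lambda3 > 0) {
        val <- val + hyper$lambda3 * kernel_term_value(kernel_matrix(X, spec), state$C)
      }
      if (hyper$lambda4 > 0) val <- val + hyper$lambda4 * inext_residual(X, state$l, skel)
      Q <- (target - project(cams, X)) * state$trusted
      val + (state$mu / 2) * (sum((X - anchor)^2) + sum(Q * Q))
    },
    gr = function(xvec) {
      X <- matrix(xvec, 3 * np, nf)
      G <- matrix(0, 3 * np, nf)
      if (hyper$lambda3 > 0) {
        G <- G + hyper$lambda3 * kernel_term_gradient(X, state$C, spec)
      }
      if (hyper$lambda4 > 0) G <- G + hyper$lambda4 * inext_gradient(X, state$l, skel)
      Q <- (target - project(cams, X)) * state$trusted
      as.vector(G + state$mu * (X - anchor) - state$mu * backproject(cams, Q))
    }
  )
}

#' Inner solve of the X subproblem
#'
#' Minimizes the nonlinear least-squares subproblem in `X` — kernel term,
#' inextensibility residual and the two quadratic penalty terms — by a bounded
#' quasi-Newton (L-BFGS-B) loop warm-started at the current `X`. The returned
#' matrix never has a larger subproblem objective than the warm start.
#' Coincident connected joints (where the inextensibility gradient is
#' undefined) are perturbed by `1e-6` with a warning.
#'
#' @param state solver state list with elements `X`, `Xhat`, `Z`, `E`, `C`,
#'   `l`, `Gamma1`, `Gamma3`, `mu`, `W`, `np`, `nf`.
#' @param hyper a [tuns_params()].
#' @param cams a [camera_track()].
#' @param skel a [skeleton()].
#' @param spec a resolved [kernel_spec()].
#' @return updated motion matrix X.
#' @export
update_X <- function(state, hyper, cams, skel, spec) {
  X <- state$X
  if (hyper$lambda4 > 0) {
    L <- bone_lengths_by_frame(X, skel)
    if (any(L <= 1e-9)) {
      warning("coincident connected joints; perturbing by 1e-6", call. = FALSE)
      X <- X + 1e-6 * sin(seq_along(X))
      state$X <- X
    }
  }
  sp <- x_subproblem(state, hyper, cams, skel, spec)
  f0 <- sp$fn(as.vector(X))
  opt <- stats::optim(as.vector(X), fn = sp$fn, gr = sp$gr, method = "L-BFGS-B",
                      control = list(maxit = hyper$inner_iter, factr = 1e7))
  if (!is.finite(opt$value)) {
    cond <- structure(class = c("tuns_solver_error", "error", "condition"),
                      list(message = "non-finite objective in X subproblem",
                           call = NULL, state = state))
    stop(cond)
  }
  if (opt$value <= f0) matrix(opt$par, nrow(X), ncol(X)) else X
}

#' Dual ascent and penalty schedule
#'
#' Updates the Lagrange multipliers by `Gamma <- Gamma + mu * residual` for
#' the three constraints (`W = R X# + E`, `C = I - Z`, `X = Xhat`), raises
#' `mu <- min(rho * mu, mu_max)` and appends the triple of constraint
#' residual norms, each normalized by `max(1, ||W||_F)`, to the history.
#'
#' @param state solver state list (see [update_X()]), additionally holding
#'   `Gamma2` and `residuals`.
#' @param W observation matrix used in the residuals.
#' @param cams a [camera_track()].
#' @param hyper a [tuns_params()] providing `rho` and `mu_max`.
#' @return updated state list.
#' @export
update_multipliers <- function(state, W, cams, hyper) {
  r1 <- W - project(cams, state$X) - state$E
  r2 <- state$C - diag(state$nf) + state$Z
  r3 <- state$X - state$Xhat
  state$Gamma1 <- state$Gamma1 + state$mu * r1
  state$Gamma2 <- state$Gamma2 + state$mu * r2
  state$Gamma3 <- state$Gamma3 + state$mu * r3
  state$mu <- min(hyper$rho * state$mu, hyper$mu_max)
  den <- max(1, fnorm(W))
  state$residuals <- rbind(state$residuals,
                           c(fnorm(r1), fnorm(r2), fnorm(r3)) / den)
  state
}

init_state <- function(W, cams, skel, hyper, trim = TRUE) {
  nf <- n_frames(cams)
  np <- ncol(W)
  n_basis <- hyper$n_basis
  if (is.null(n_basis)) n_basis <- max(2, ceiling(0.1 * nf))
  n_basis <- min(as.integer(n_basis), nf)
  X0 <- init_trajectory_dct(W, cams, n_basis)
  trusted <- matrix(TRUE, 2 * nf, np)
  # Robust initialization: joints whose refit residual is out of scale with
  # the observations themselves (gross tracking outliers, not mere temporal
  # underfit) are dropped from the least-squares design and the fit redone
  # per joint. The flagged cells stay excluded from the quadratic data term
  # of the ALM — their residual lives entirely in the sparse error matrix,
  # so the dual variables never chase them.
  if (trim) {
    for (round in 1:2) {
      r <- W - project(cams, X0)
      cut <- max(6 * stats::mad(r), 0.25 * sqrt(mean(W^2)))
      bad <- abs(r[2 * seq_len(nf) - 1, , drop = FALSE]) > cut |
        abs(r[2 * seq_len(nf), , drop = FALSE]) > cut
      if (cut <= 0 || !any(bad)) break
      trusted[2 * seq_len(nf) - 1, ] <- !bad
      trusted[2 * seq_len(nf), ] <- !bad
      X0 <- masked_trajectory_dct(W, cams, n_basis, trusted)
    }
  }
  r0 <- W - project(cams, X0)
  E0 <- r0 * !trusted
  list(X = X0, Xhat = X0, Z = matrix(0, nf, nf), C = matrix(0, nf, nf),
       E = E0, trusted = trusted, l = update_l(X0, skel),
       Gamma1 = matrix(0, 2 * nf, np), Gamma2 = matrix(0, nf, nf),
       Gamma3 = matrix(0, 3 * np, nf), mu = hyper$mu0, iter = 0L,
       W = W, np = np, nf = nf, residuals = NULL)
}

# per-frame 2D centroid removal; returns list(W, centers 2 x NF)
center_tracks <- function(W) {
  nf <- nrow(W) %/% 2L
  centers <- matrix(0, 2, nf)
  for (f in seq_len(nf)) {
    m <- rowMeans(W[frame_rows2(f), , drop = FALSE])
    centers[, f] <- m
    W[frame_rows2(f), ] <- W[frame_rows2(f), ] - m
  }
  list(W = W, centers = centers)
}

run_alm <- function(W, cams, skel, hyper, what_updater = NULL) {
  state <- init_state(W, cams, skel, hyper, trim = is.null(what_updater))
  spec <- resolve_bandwidth(hyper$kernel, state$X)   # bandwidth frozen at X0
  K <- kernel_matrix(state$X, spec)
  converged <- FALSE
  for (k in seq_len(hyper$max_iter)) {
    state$iter <- k
    state$Z <- update_Z(state$C, state$Gamma2, state$mu)
    state$Xhat <- update_Xhat(state$X, state$Gamma3, state$mu, hyper$lambda1)
    state$X <- update_X(state, hyper, cams, skel, spec)
    if (!all(is.finite(state$X))) {
      cond <- structure(class = c("tuns_solver_error", "error", "condition"),
                        list(message = "non-finite solver state", call = NULL,
                             state = state))
      stop(cond)
    }
    K <- kernel_matrix(state$X, spec)
    Xsharp <- to_framewise(state$X)
    Es <- update_E(state$W, Xsharp, state$Gamma1, state$mu, hyper$lambda2, cams)
    # untrusted entries carry their full residual so the constraint is met
    # there exactly and the multiplier stays at zero
    Efull <- state$W - project_sharp(cams, Xsharp) + state$Gamma1 / state$mu
    state$E <- Es * state$trusted + Efull * !state$trusted
    if (!is.null(what_updater)) {
      state$W <- what_updater(state, cams)
      W <- state$W
    }
    state$C <- update_C(K, state$Z, state$Gamma2, state$mu, hyper$lambda3)
    state$l <- update_l(state$X, skel)
    state <- update_multipliers(state, state$W, cams, hyper)
    res <- state$residuals[nrow(state$residuals), ]
    if (hyper$verbose && (k %% 50 == 0 || k == 1)) {
      message(sprintf("iter %4d  mu=%.2e  res=(%.2e, %.2e, %.2e)",
                      k, state$mu, res[1], res[2], res[3]))
    }
    if (max(res) < hyper$tol) {
      converged <- TRUE
      break
    }
  }
  state$converged <- converged
  state$kernel_resolved <- spec
  state
}

#' Reconstruct 3D motion from 2D tracks and known rotations
#'
#' Runs the full ALM loop: initialization by the DCT trajectory fit, then
#' alternating closed-form/quasi-Newton updates of `{Z, Xhat, X, E, C, l}`
#' followed by dual ascent, until the largest normalized constraint residual
#' drops below `tol` or `max_iter` is reached. Preprocessing (on by default)
#' removes the per-frame 2D centroid and rescales the tracks to unit RMS; the
#' returned quantities are mapped back to input units (the per-frame image
#' translation, if removed, is not re-applied to the 3D output — the solution
#' lives in the centred frame).
#'
#' @param W observation matrix, 2NF x NP (rows 2f-1, 2f are the image x/y of
#'   all joints at frame f).
#' @param cams a [camera_track()].
#' @param skel a [skeleton()].
#' @param hyper a [tuns_params()].
#' @return object of class `tuns_fit`: `X` (3NP x NF estimate), `Z` (NF x NF
#'   affinity), `E` (sparse reprojection error, input units), `l` (bone
#'   lengths, input units), `C`, `converged`, `iterations`, `residuals`
#'   (one row per iteration: the three normalized constraint residuals),
#'   `scale`, `centers`, and the hyperparameters used.
#' @export
reconstruct <- function(W, cams, skel, hyper = tuns_params()) {
  W <- as.matrix(W)
  check_finite(W, "W")
  nf <- n_frames(cams)
  if (nrow(W) != 2 * nf) stop_input("'W' must have 2*NF rows matching the camera track")
  if (ncol(W) != skel$num_joints) stop_input("'W' must have NP columns matching the skeleton")
  centers <- NULL
  if (hyper$center_tracks) {
    ct <- center_tracks(W)
    W <- ct$W
    centers <- ct$centers
  }
  s <- sqrt(mean(W^2))
  if (s <= 0) stop_input("'W' has zero scale")
  state <- run_alm(W / s, cams, skel, hyper)
  structure(list(X = state$X * s, Z = state$Z, E = state$E * s,
                 l = state$l * s, C = state$C, converged = state$converged,
                 iterations = state$iter, residuals = state$residuals,
                 scale = s, centers = centers, hyper = hyper,
                 kernel = state$kernel_resolved),
            class = "tuns_fit")
}

#' @export
print.tuns_fit <- function(x, ...) {
  d <- motion_dims(x$X)
  res <- x$residuals[nrow(x$residuals), ]
  cat(sprintf("<tuns_fit: %d joints x %d frames, %d iterations, %s>\n",
              d$np, d$nf, x$iterations,
              if (x$converged) "converged" else "not converged"))
  cat(sprintf("  final residuals: reprojection %.3e, affinity %.3e, shape %.3e\n",
              res[1], res[2], res[3]))
  invisible(x)
}
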