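test_that("update_Z is the exact nuclear-norm proximal step", {
  nf <- 6
  # C = 0, Gamma2 = 0, mu = 2: identity has singular values 1 -> 0.5 I
  expect_equal(update_Z(matrix(0, nf, nf), matrix(0, nf, nf), 2),
               0.5 * diag(nf), tolerance = 1e-12)
  # large mu: threshold vanishes
  C <- rand_mat(nf, nf, 1) * 0.1
  G2 <- rand_mat(nf, nf, 2) * 0.1
  expect_equal(update_Z(C, G2, 1e9), diag(nf) - C - G2 / 1e9, tolerance = 1e-6)
  expect_error(update_Z(C, G2, 0), "mu")
  # local optimality of the subproblem objective against perturbations
  mu <- 1.7
  Z <- update_Z(C, G2, mu)
  obj <- function(Zc) sum(svd(Zc)$d) + (mu / 2) * sum((Zc - (diag(nf) - C - G2 / mu))^2)
  f0 <- obj(Z)
  withr::with_seed(3, {
    for (i in 1:200) expect_gte(obj(Z + matrix(rnorm(nf^2, sd = 0.03), nf, nf)), f0 - 1e-12)
  })
})

test_that("update_Xhat applies the scaled thresholding of the shape prior", {
  X <- rand_mat(9, 6, 4)
  G3 <- rand_mat(9, 6, 5) * 0.2
  expect_equal(update_Xhat(X, G3, 2, 0), X + G3 / 2, tolerance = 1e-12)
  # rank-1 closed form: Xhat = max(1 - lambda1/(mu s), 0) X
  u <- rnorm(9); v <- rnorm(6)
  X1 <- outer(u, v)
  s <- sqrt(sum(u^2)) * sqrt(sum(v^2))
  lam <- 0.3; mu <- 1.2
  expect_equal(update_Xhat(X1, 0 * X1, mu, lam),
               max(1 - lam / (mu * s), 0) * X1, tolerance = 1e-10)
  # proximal optimality via perturbation sampling
  mu <- 2.5; lam <- 0.8
  Xh <- update_Xhat(X, G3, mu, lam)
  obj <- function(Y) lam * sum(svd(Y)$d) + (mu / 2) * sum((Y - (X + G3 / mu))^2)
  f0 <- obj(Xh)
  withr::with_seed(6, {
    for (i in 1:200) expect_gte(obj(Xh + matrix(rnorm(54, sd = 0.03), 9, 6)), f0 - 1e-12)
  })
})

test_that("update_E shrinks the reprojection residual entrywise", {
  cams <- make_rotating_camera(5, 10)
  X <- rand_mat(9, 5, 7)
  Xs <- to_framewise(X)
  W <- project(cams, X)
  G1 <- matrix(0, 10, 3)
  # noiseless observations -> E = 0
  expect_equal(update_E(W, Xs, G1, 2, 1, cams), matrix(0, 10, 3))
  # single outlier of magnitude 10 with threshold 1 -> entry 9
  Wo <- W
  Wo[3, 2] <- Wo[3, 2] + 10
  E <- update_E(Wo, Xs, G1, 1, 1, cams)
  expect_equal(E[3, 2], 9, tolerance = 1e-12)
  expect_equal(sum(E != 0), 1)
  # per-entry 1-D oracle: grid search on the scalar subproblem
  mu <- 1.4; lam <- 0.6
  Wr <- W + rand_mat(10, 3, 8) * 0.5
  G1r <- rand_mat(10, 3, 9) * 0.3
  Er <- update_E(Wr, Xs, G1r, mu, lam, cams)
  Tm <- Wr - project(cams, X) + G1r / mu
  grid <- seq(-2, 2, by = 1e-3)
  for (idx in c(1, 7, 23)) {
    vals <- lam * abs(grid) + (mu / 2) * (grid - Tm[idx])^2
    expect_lt(abs(Er[idx] - grid[which.min(vals)]), 2e-3)
  }
})

test_that("update_C satisfies its stationarity equation", {
  nf <- 7
  X <- rand_mat(12, nf, 10)
  K <- kernel_matrix(X, kernel_spec("rbf", 1.3))
  Z <- rand_mat(nf, nf, 11) * 0.2
  G2 <- rand_mat(nf, nf, 12) * 0.2
  mu <- 1.9; lam <- 0.7
  C <- update_C(K, Z, G2, mu, lam)
  resid <- 2 * lam * K %*% C + mu * (C - (diag(nf) - Z)) + G2
  expect_lt(max(abs(resid)), 1e-8)
  # lambda3 = 0 reduces to the explicit expression
  expect_equal(update_C(K, Z, G2, mu, 0), diag(nf) - Z - G2 / mu, tolerance = 1e-10)
  # Z = I, Gamma2 = 0 -> C = 0
  expect_equal(update_C(K, diag(nf), matrix(0, nf, nf), mu, lam),
               matrix(0, nf, nf), tolerance = 1e-10)
})

test_that("multiplier updates follow dual ascent with a capped schedule", {
  st <- toy_state()
  cams <- make_rotating_camera(st$nf, 12)
  hyper <- tuns_params(rho = 1.1, mu0 = 1e-3, mu_max = 1e8)
  # consistent state: residuals vanish, multipliers unchanged
  st0 <- st
  st0$E <- st0$W - project(cams, st0$X)
  st0$C <- diag(st0$nf) - st0$Z
  st0$Xhat <- st0$X
  out <- update_multipliers(st0, st0$W, cams, hyper)
  expect_equal(out$Gamma1, st0$Gamma1, tolerance = 1e-12)
  expect_equal(out$Gamma2, st0$Gamma2, tolerance = 1e-12)
  expect_equal(out$Gamma3, st0$Gamma3, tolerance = 1e-12)
  expect_equal(as.vector(out$residuals), c(0, 0, 0), tolerance = 1e-12)
  # mu follows the geometric schedule and caps at mu_max
  st1 <- st; st1$mu <- 1e-3
  for (i in 1:10) st1 <- update_multipliers(st1, st1$W, cams, hyper)
  expect_equal(st1$mu, 1e-3 * 1.1^10, tolerance = 1e-12)
  st2 <- st; st2$mu <- 1e8
  st2 <- update_multipliers(st2, st2$W, cams, hyper)
  expect_equal(st2$mu, 1e8)
})

test_that("DCT initializer fits observable structure and nests by basis size", {
  sk <- make_skeleton("stick13")
  # static body: the DC basis suffices and reprojection is exact
  Xr <- generate_action(sk, "swing", 10, amplitude = 0)
  cams <- make_rotating_camera(10, 8)
  W <- project(cams, Xr)
  X0 <- init_trajectory_dct(W, cams, 1, damping = 0)
  expect_lt(max(abs(project(cams, X0) - W)), 1e-8)
  # reprojection residual is non-increasing in n_basis (exact LS route)
  Xm <- generate_action(sk, "walk_cycle", 12, seed = 2)
  cams2 <- make_rotating_camera(12, 5)
  Wm <- project(cams2, Xm)
  res <- sapply(c(1, 2, 4, 8, 12), function(nb) {
    X0 <- suppressWarnings(init_trajectory_dct(Wm, cams2, nb, damping = 0))
    sqrt(sum((Wm - project(cams2, X0))^2))
  })
  expect_true(all(diff(res) <= 1e-8))
  # with the full basis the exact fit matches the zero-depth lift's residual
  Xlift <- to_pointwise(do.call(rbind, lapply(1:12, function(f) {
    t(cams2[, , f]) %*% Wm[(2 * f - 1):(2 * f), ]
  })))
  X0d <- suppressWarnings(init_trajectory_dct(Wm, cams2, 12, damping = 0))
  expect_lte(sqrt(sum((Wm - project(cams2, X0d))^2)),
             sqrt(sum((Wm - project(cams2, Xlift))^2)) + 1e-8)
  expect_error(init_trajectory_dct(Wm, cams2, 0), "n_basis")
})

test_that("the X subproblem solves its quadratic special case in closed form", {
  st <- toy_state()
  cams <- make_rotating_camera(st$nf, 15)
  skel <- skeleton(st$np, rbind(c(1, 2), c(2, 3)))
  st$E <- matrix(0, 2 * st$nf, st$np)
  st$Gamma1 <- st$Gamma1 * 0
  st$Gamma3 <- st$Gamma3 * 0
  st$Xhat <- st$X
  st$l <- update_l(st$X, skel)
  hyper <- tuns_params(lambda3 = 0, lambda4 = 0, inner_iter = 500)
  Xsol <- update_X(st, hyper, cams, skel, kernel_spec("rbf", 1))
  # closed form per frame/joint: (I + R_f' R_f) x = x0 + R_f' w
  Xref <- st$X
  for (f in seq_len(st$nf)) {
    Rf <- cams[, , f]
    A <- diag(3) + t(Rf) %*% Rf
    for (p in seq_len(st$np)) {
      x0 <- st$X[(3 * p - 2):(3 * p), f]
      w <- st$W[(2 * f - 1):(2 * f), p]
      Xref[(3 * p - 2):(3 * p), f] <- solve(A, x0 + t(Rf) %*% w)
    }
  }
  expect_lt(max(abs(Xsol - Xref)), 1e-6)
})

test_that("the full inner objective gradient matches finite differences", {
  np <- 5; nf <- 8
  st <- toy_state(np = np, nf = nf, seed = 21)
  cams <- make_rotating_camera(nf, 11)
  skel <- skeleton(np, rbind(c(1, 2), c(2, 3), c(3, 4), c(3, 5)))
  st$l <- update_l(st$X, skel) * 0.9
  hyper <- tuns_params(lambda3 = 0.8, lambda4 = 1.3)
  spec <- kernel_spec("rbf", 1.6)
  sp <- tuns:::x_subproblem(st, hyper, cams, skel, spec)
  x0 <- as.vector(st$X + 0.05 * rand_mat(3 * np, nf, 22))
  expect_lt(rel_err(sp$gr(x0), fd_gradient(sp$fn, x0)), 1e-4)
})

test_that("the inner X solve never increases its objective", {
  st <- toy_state(np = 4, nf = 6, seed = 31)
  cams <- make_rotating_camera(st$nf, 9)
  skel <- skeleton(4, rbind(c(1, 2), c(2, 3), c(2, 4)))
  st$l <- update_l(st$X, skel)
  hyper <- tuns_params(lambda3 = 1, lambda4 = 1, inner_iter = 15)
  spec <- kernel_spec("rbf", 1.2)
  sp <- tuns:::x_subproblem(st, hyper, cams, skel, spec)
  f0 <- sp$fn(as.vector(st$X))
  Xn <- update_X(st, hyper, cams, skel, spec)
  expect_lte(sp$fn(as.vector(Xn)), f0 + 1e-12)
})

test_that("reconstruction is deterministic and tolerates outlier-free L1", {
  sc <- make_scene(actions = "swing", n_frames = 14, deg_per_frame = 6, seed = 5)
  hp <- tuns_params(max_iter = 60, center_tracks = FALSE)
  f1 <- reconstruct(sc$W_clean, sc$cams, sc$skeleton, hp)
  f2 <- reconstruct(sc$W_clean, sc$cams, sc$skeleton, hp)
  expect_identical(f1$residuals, f2$residuals)  # bit-identical histories
  expect_identical(f1$X, f2$X)
  # outlier-free tracks with a strong L1 weight keep E essentially empty
  hp2 <- tuns_params(lambda2 = 100, max_iter = 150, center_tracks = FALSE)
  f3 <- reconstruct(sc$W_clean, sc$cams, sc$skeleton, hp2)
  expect_lt(max(abs(f3$E)), 1e-6)
})

test_that("hyperparameter validation reports all violations", {
  expect_error(tuns_params(rho = 0.9), "rho")
  expect_error(tuns_params(tol = -1), "tol")
  err <- tryCatch(tuns_params(rho = 0.5, tol = 0, lambda2 = -1), error = identity)
  expect_match(conditionMessage(err), "rho")
  expect_match(conditionMessage(err), "tol")
  expect_match(conditionMessage(err), "lambda2")
})
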