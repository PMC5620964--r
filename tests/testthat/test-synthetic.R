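test_that("skeleton presets are connected trees", {
  for (preset in c("stick13", "stick15")) {
    sk <- make_skeleton(preset)
    nb <- nrow(sk$bones)
    expect_equal(nb, sk$num_joints - 1)  # tree edge count
    expect_true(all(sk$bones >= 1 & sk$bones <= sk$num_joints))
    # connected and acyclic: breadth-first traversal reaches every joint once
    adj <- lapply(seq_len(sk$num_joints), function(j) {
      c(sk$bones[sk$bones[, 1] == j, 2], sk$bones[sk$bones[, 2] == j, 1])
    })
    seen <- c(1L); frontier <- c(1L)
    while (length(frontier)) {
      nxt <- setdiff(unlist(adj[frontier]), seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    expect_setequal(seen, seq_len(sk$num_joints))
    expect_true(all(sk$rest_lengths > 0))
  }
  expect_error(make_skeleton("stick99"))
})

test_that("forward kinematics conserves bone lengths exactly", {
  sk <- make_skeleton("stick13")
  for (kind in c("swing", "walk_cycle", "reach", "crouch")) {
    X <- generate_action(sk, kind, 20, seed = 3)
    L <- sapply(seq_len(nrow(sk$bones)), function(b) {
      p <- sk$bones[b, 1]; q <- sk$bones[b, 2]
      D <- X[(3 * p - 2):(3 * p), ] - X[(3 * q - 2):(3 * q), ]
      sqrt(colSums(D * D))
    })
    expect_lt(max(abs(t(L) - sk$rest_lengths)), 1e-9)
  }
})

test_that("actions are deterministic, distinct, and freeze at zero amplitude", {
  sk <- make_skeleton("stick13")
  X1 <- generate_action(sk, "swing", 15, seed = 5)
  X2 <- generate_action(sk, "swing", 15, seed = 5)
  expect_identical(X1, X2)
  X3 <- generate_action(sk, "reach", 15, seed = 5)
  expect_gt(sqrt(sum((X1 - X3)^2)), 0.1)
  X0 <- generate_action(sk, "crouch", 8, amplitude = 0)
  expect_equal(X0, X0[, c(1, 1, 1, 1, 1, 1, 1, 1)], tolerance = 1e-15)
})

test_that("concatenation preserves length bookkeeping and labels", {
  sk <- make_skeleton("stick13")
  A <- generate_action(sk, "swing", 10, seed = 1)
  B <- generate_action(sk, "reach", 14, seed = 2)
  cc <- concat_actions(list(A, B))
  expect_equal(ncol(cc$X), 24)
  expect_equal(cc$labels, rep(1:2, c(10, 14)))
  expect_identical(concat_actions(list(A))$X, A)  # identity on one clip
  # labels partition the frames and match the source lengths
  expect_equal(as.vector(table(cc$labels)), c(10, 14))
  # cross-fade keeps frame count, touches only the junction
  cf <- concat_actions(list(A, B), fade = 3)
  expect_equal(ncol(cf$X), 24)
  expect_identical(cf$X[, 1:10], cc$X[, 1:10])
  expect_identical(cf$X[, 14:24], cc$X[, 14:24])
  expect_false(identical(cf$X[, 11], cc$X[, 11]))
  expect_error(concat_actions(list(A, A[1:36, ])), "skeleton")
})

test_that("observation corruption is seeded and calibrated", {
  sk <- make_skeleton("stick13")
  X <- generate_action(sk, "swing", 10, seed = 1)
  cams <- make_rotating_camera(10, 2)
  W <- project(cams, X)
  expect_identical(corrupt_observations(W, 0, 0, seed = 1)[, ], W[, ])
  # exact outlier count: 10% of 10 x 13 = 13 cells
  Wo <- corrupt_observations(W, 0, 0.1, outlier_scale = 2, seed = 2)
  cells <- attr(Wo, "outlier_cells")
  expect_length(cells, 13)
  changed <- which(colSums(abs(matrix(Wo - W, 2))) > 0)  # per (f, p) cell
  expect_setequal(changed, cells)
  expect_identical(corrupt_observations(W, 0.1, 0.1, seed = 3),
                   corrupt_observations(W, 0.1, 0.1, seed = 3))
  # empirical noise sd within 5%
  Wb <- matrix(0, 200, 50)
  Wn <- corrupt_observations(Wb, noise_sd = 0.5, seed = 4)
  expect_lt(abs(sd(as.vector(Wn)) - 0.5) / 0.5, 0.05)
  expect_error(corrupt_observations(W, -1), "noise_sd")
  expect_error(corrupt_observations(W, 0, 0.9), "outlier_frac")
})

test_that("scenes assemble consistently", {
  sc <- make_scene(actions = c("swing", "crouch"), n_frames = c(8, 12),
                   deg_per_frame = 3, noise_sd = 0.01, outlier_frac = 0.05,
                   seed = 9)
  expect_equal(ncol(sc$X_gt), 20)
  expect_equal(dim(sc$W_clean), c(40L, 13L))
  expect_equal(length(sc$action_labels), 20)
  expect_equal(sc$W_clean, project(sc$cams, sc$X_gt), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(sc$W_noisy[, ], sc$W_clean[, ])))
  # ground truth conserves rest bone lengths (criterion for update_l recovery)
  expect_lt(max(abs(update_l(sc$X_gt, sc$skeleton) - sc$skeleton$rest_lengths)), 1e-9)
})
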