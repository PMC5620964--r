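hm_fixture <- function(nf = 6, seed = 2) {
  sk <- make_skeleton("stick13")
  X <- generate_action(sk, "swing", nf, seed = seed)
  cams <- make_rotating_camera(nf, 5)
  W <- project(cams, X)
  list(sk = sk, X = X, cams = cams, W = W,
       stack = synth_heightmaps(W, grid = 48, sigma_px = 2, seed = seed))
}

test_that("heightmap score is the negated interpolated sum", {
  fx <- hm_fixture()
  # all-zero heightmaps score 0 everywhere
  z <- heightmap_stack(array(0, c(8, 8, 2, 3)), origin = c(0, 0), scale = 1)
  expect_equal(heightmap_score(z, matrix(2, 4, 3)), 0)
  # delta-like peak of value 1 at a known pixel scores -1 there
  m <- array(0, c(16, 16, 1, 1))
  m[10, 10, 1, 1] <- 1
  st <- heightmap_stack(m, origin = c(0, 0), scale = 1)
  expect_equal(heightmap_score(st, matrix(c(9, 9), 2, 1)), -1)  # pixel (10,10) is image (9,9)
  # clutter-free synthetic stacks peak at the true joints (bilinear
  # interpolation between pixel samples costs a few percent of the peak)
  expect_equal(-heightmap_score(fx$stack, fx$W) / (6 * 13), 1, tolerance = 0.05)
})

test_that("bilinear interpolation matches a two-loop reference", {
  fx <- hm_fixture()
  st <- fx$stack
  ref_interp <- function(map, r, c) {
    r0 <- min(floor(r), nrow(map) - 1); c0 <- min(floor(c), ncol(map) - 1)
    tr <- r - r0; tc <- c - c0
    (1 - tr) * ((1 - tc) * map[r0, c0] + tc * map[r0, c0 + 1]) +
      tr * ((1 - tc) * map[r0 + 1, c0] + tc * map[r0 + 1, c0 + 1])
  }
  withr::with_seed(7, {
    for (i in 1:50) {
      f <- sample(st$nf, 1); p <- sample(st$np, 1)
      r <- runif(1, 1, st$h - 1); cc <- runif(1, 1, st$w - 1)
      Wq <- matrix(0, 2 * st$nf, st$np)
      Wq[2 * f - 1, p] <- (cc - 1) / st$scale + st$origin[1]
      Wq[2 * f, p] <- (r - 1) / st$scale + st$origin[2]
      got <- tuns:::interp_stack(st, Wq)$value[(p - 1) * st$nf + f]
      expect_equal(got, ref_interp(st$maps[, , f, p], r, cc), tolerance = 1e-10)
    }
  })
})

test_that("synthetic heightmaps are calibrated and seeded", {
  fx <- hm_fixture()
  st <- fx$stack
  # clutter-free: modes within one pixel of the truth
  expect_lt(max(abs(st$modes - fx$W)) * st$scale, 1)
  # determinism contract
  s2 <- synth_heightmaps(fx$W, grid = 48, sigma_px = 2, seed = 2)
  expect_identical(st$maps, s2$maps)
  s3 <- synth_heightmaps(fx$W, grid = 48, sigma_px = 2, clutter = 0.4, seed = 3)
  s4 <- synth_heightmaps(fx$W, grid = 48, sigma_px = 2, clutter = 0.4, seed = 4)
  expect_false(identical(s3$maps, s4$maps))
  expect_error(synth_heightmaps(fx$W, sigma_px = 0), "sigma_px")
  expect_error(synth_heightmaps(fx$W, clutter = 1), "clutter")
})

test_that("update_What balances the anchor and the heightmap evidence", {
  fx <- hm_fixture(nf = 4)
  st <- fx$stack
  anchor <- fx$W + 0.05
  # lambda5 = 0: the anchor is returned exactly
  Wq <- tuns:::update_what_core(st, anchor, mu = 3, lambda5 = 0)
  expect_equal(Wq, anchor, tolerance = 1e-12)
  # tiny mu with a unimodal bump: solution moves to the heightmap mode
  Wm <- tuns:::update_what_core(st, anchor, mu = 1e-9, lambda5 = 1)
  expect_lt(max(abs(Wm - st$modes)) * st$scale, 1.5)
  # flat heightmaps: anchor returned (data term uninformative)
  flat <- heightmap_stack(array(0.5, c(12, 12, 4, 13)), origin = st$origin,
                          scale = st$scale)
  expect_equal(tuns:::update_what_core(flat, anchor, 2, 1), anchor, tolerance = 1e-9)
})

test_that("update_What matches a dense grid search on a Gaussian/quadratic case", {
  # single map: Gaussian centred at c, quadratic anchor at a
  g <- 41
  sigma_px <- 3
  ctr <- c(25, 17)  # (row, col)
  m <- array(exp(-(outer((1:g - ctr[1])^2, (1:g - ctr[2])^2, "+")) / (2 * sigma_px^2)),
             c(g, g, 1, 1))
  st <- heightmap_stack(m, origin = c(0, 0), scale = 1)
  anchor <- matrix(c(10, 30), 2, 1)  # image coords (x = col - 1, y = row - 1)
  mu <- 0.02; lam <- 1
  got <- tuns:::update_what_core(st, anchor, mu, lam)
  # dense grid-search oracle at 0.1 px resolution
  xs <- seq(1, g - 1, by = 0.1)
  best <- c(NA, NA); bestv <- Inf
  for (x in xs) {
    for (y in xs) {
      h <- exp(-((y + 1 - ctr[1])^2 + (x + 1 - ctr[2])^2) / (2 * sigma_px^2))
      v <- -lam * h + (mu / 2) * ((x - anchor[1])^2 + (y - anchor[2])^2)
      if (v < bestv) { bestv <- v; best <- c(x, y) }
    }
  }
  expect_lt(max(abs(got - best)), 0.5)
})

test_that("marker-less reconstruction approaches the marker-based run", {
  nf <- 12
  sk <- make_skeleton("stick13")
  X <- generate_action(sk, "swing", nf, seed = 4)
  cams <- make_rotating_camera(nf, 8)
  W <- project(cams, X)
  stack <- synth_heightmaps(W, grid = 48, sigma_px = 2, seed = 4)
  hp <- tuns_params(max_iter = 80, center_tracks = FALSE)
  fml <- reconstruct_markerless(stack, cams, sk, hp)
  expect_s3_class(fml, "tuns_fit")
  # recovered observations stay within a pixel of the truth
  expect_lt(sqrt(mean((fml$What - W)^2)) * stack$scale, 1)
  # determinism
  fml2 <- reconstruct_markerless(stack, cams, sk, hp)
  expect_identical(fml$X, fml2$X)
})

test_that("heightmap stacks round-trip through the packed binary format", {
  fx <- hm_fixture(nf = 3)
  dir <- tempfile()
  write_heightmaps(fx$stack, dir)
  st2 <- read_heightmaps(dir)
  expect_equal(st2$maps, fx$stack$maps, tolerance = 1e-6)  # float32 precision
  expect_equal(st2$origin, fx$stack$origin, tolerance = 1e-12)
  expect_equal(st2$scale, fx$stack$scale, tolerance = 1e-12)
})
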