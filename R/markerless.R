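#' Heightmap stack
#'
#' Per-frame, per-joint nonnegative score grids produced by a 2D joint
#' detector, plus the mapping from continuous image coordinates to pixel
#' indices: `col = (x - origin[1]) * scale + 1`,
#' `row = (y - origin[2]) * scale + 1` (first grid axis is vertical; pixel
#' centres sit at integer coordinates; values between pixels are obtained by
#' bilinear interpolation).
#'
#' @param maps numeric array `H x W x NF x NP` of nonnegative values.
#' @param origin length-2 numeric: image coordinates of pixel (1, 1).
#' @param scale pixels per image unit (> 0).
#' @return object of class `heightmap_stack` with precomputed per-map modes
#'   (`modes`, a 2NF x NP matrix of argmax image coordinates).
#' @export
heightmap_stack <- function(maps, origin = c(0, 0), scale = 1) {
  if (!is.array(maps) || length(dim(maps)) != 4L) {
    stop_input("'maps' must be an H x W x NF x NP array")
  }
  if (any(maps < 0)) stop_input("heightmap values must be nonnegative")
  check_scalar(scale, "scale")
  if (scale <= 0) stop_input("'scale' must be > 0")
  st <- structure(list(maps = maps, origin = as.numeric(origin), scale = scale,
                       nf = dim(maps)[3], np = dim(maps)[4],
                       h = dim(maps)[1], w = dim(maps)[2]),
                  class = "heightmap_stack")
  st$modes <- stack_modes(st)
  st
}

#' @export
print.heightmap_stack <- function(x, ...) {
  cat(sprintf("<heightmap_stack: %dx%d grids, %d frames x %d joints>\n",
              x$h, x$w, x$nf, x$np))
  invisible(x)
}

# argmax image coordinates per (f, p), 2NF x NP
stack_modes <- function(stack) {
  modes <- matrix(0, 2 * stack$nf, stack$np)
  for (p in seq_len(stack$np)) {
    for (f in seq_len(stack$nf)) {
      i <- which.max(stack$maps[, , f, p])
      r <- (i - 1) %% stack$h + 1
      cc <- (i - 1) %/% stack$h + 1
      modes[frame_rows2(f), p] <- c((cc - 1) / stack$scale + stack$origin[1],
                                    (r - 1) / stack$scale + stack$origin[2])
    }
  }
  modes
}

# vectorized bilinear interpolation (and optional gradient) of the stack at
# the coordinates in What (2NF x NP, image units). Out-of-bounds coordinates
# are clamped to the grid.
interp_stack <- function(stack, What, gradient = FALSE, warn_oob = TRUE) {
  nf <- stack$nf; np <- stack$np; H <- stack$h; Wd <- stack$w
  xs <- What[2 * seq_len(nf) - 1, , drop = FALSE]
  ys <- What[2 * seq_len(nf), , drop = FALSE]
  cc <- (as.vector(xs) - stack$origin[1]) * stack$scale + 1
  rr <- (as.vector(ys) - stack$origin[2]) * stack$scale + 1
  oob <- cc < 1 | cc > Wd | rr < 1 | rr > H
  if (warn_oob && any(oob)) {
    warning(sprintf("%d heightmap coordinates out of bounds; clamped", sum(oob)),
            call. = FALSE)
  }
  cc <- pmin(pmax(cc, 1), Wd)
  rr <- pmin(pmax(rr, 1), H)
  c0 <- pmin(floor(cc), Wd - 1); r0 <- pmin(floor(rr), H - 1)
  if (Wd == 1) c0 <- rep(1, length(cc))
  if (H == 1) r0 <- rep(1, length(rr))
  tx <- cc - c0; ty <- rr - r0
  fp <- rep(seq_len(nf * np), each = 1)          # map index per point
  base <- (fp - 1) * H * Wd
  idx <- function(r, ci) base + (ci - 1) * H + r
  v00 <- stack$maps[idx(r0, c0)]
  v10 <- if (H > 1) stack$maps[idx(r0 + 1, c0)] else v00
  v01 <- if (Wd > 1) stack$maps[idx(r0, c0 + 1)] else v00
  v11 <- if (H > 1 && Wd > 1) stack$maps[idx(r0 + 1, c0 + 1)] else v10
  val <- (1 - ty) * ((1 - tx) * v00 + tx * v01) + ty * ((1 - tx) * v10 + tx * v11)
  out <- list(value = matrix(val, nf * np))
  if (gradient) {
    dcol <- (1 - ty) * (v01 - v00) + ty * (v11 - v10)
    drow <- (1 - tx) * (v10 - v00) + tx * (v11 - v01)
    # clamp kills the gradient outside the grid
    dcol[oob] <- 0; drow[oob] <- 0
    out$dx <- dcol * stack$scale
    out$dy <- drow * stack$scale
  }
  out
}

#' Heightmap data term
#'
#' `H(What) = -sum_f sum_p h_fp(w_fp)`: the negated sum of bilinearly
#' interpolated heightmap values at the candidate 2D joint positions; lower
#' is better. Out-of-grid coordinates are clamped with a warning.
#'
#' @param stack a [heightmap_stack()].
#' @param What candidate observations, 2NF x NP (image units).
#' @return scalar score.
#' @export
heightmap_score <- function(stack, What) {
  -sum(interp_stack(stack, What)$value)
}

# Minimize, independently per (f, p):
#   -lambda5 * h_fp(w) + (mu/2) ||w - anchor_fp||^2
# seeded at the anchor and at the heightmap mode, keeping the better, then a
# vectorized backtracking gradient descent. The result is never worse than
# the objective at the anchor.
update_what_core <- function(stack, anchor, mu, lambda5, n_steps = 25) {
  nf <- stack$nf; np <- stack$np
  obj <- function(Wc) {
    ip <- interp_stack(stack, Wc, warn_oob = FALSE)
    ax <- Wc[2 * seq_len(nf) - 1, , drop = FALSE] - anchor[2 * seq_len(nf) - 1, , drop = FALSE]
    ay <- Wc[2 * seq_len(nf), , drop = FALSE] - anchor[2 * seq_len(nf), , drop = FALSE]
    matrix(-lambda5 * ip$value, nf, np) + (mu / 2) * (ax^2 + ay^2)
  }
  pick <- function(Wa, Wb) {
    fa <- obj(Wa); fb <- obj(Wb)
    better <- as.vector(fb < fa)
    xs_a <- Wa[2 * seq_len(nf) - 1, , drop = FALSE]
    ys_a <- Wa[2 * seq_len(nf), , drop = FALSE]
    xs_b <- Wb[2 * seq_len(nf) - 1, , drop = FALSE]
    ys_b <- Wb[2 * seq_len(nf), , drop = FALSE]
    xs <- ifelse(matrix(better, nf, np), xs_b, xs_a)
    ys <- ifelse(matrix(better, nf, np), ys_b, ys_a)
    out <- matrix(0, 2 * nf, np)
    out[2 * seq_len(nf) - 1, ] <- xs
    out[2 * seq_len(nf), ] <- ys
    out
  }
  Wc <- pick(anchor, stack$modes)
  step0 <- 1 / (mu + lambda5 * stack$scale^2)
  for (it in seq_len(n_steps)) {
    ip <- interp_stack(stack, Wc, gradient = TRUE, warn_oob = FALSE)
    gx <- matrix(-lambda5 * ip$dx, nf, np) +
      mu * (Wc[2 * seq_len(nf) - 1, , drop = FALSE] - anchor[2 * seq_len(nf) - 1, , drop = FALSE])
    gy <- matrix(-lambda5 * ip$dy, nf, np) +
      mu * (Wc[2 * seq_len(nf), , drop = FALSE] - anchor[2 * seq_len(nf), , drop = FALSE])
    f_cur <- obj(Wc)
    step <- matrix(step0, nf, np)
    trial <- Wc
    for (h in 1:8) {
      trial[2 * seq_len(nf) - 1, ] <- Wc[2 * seq_len(nf) - 1, ] - step * gx
      trial[2 * seq_len(nf), ] <- Wc[2 * seq_len(nf), ] - step * gy
      f_try <- obj(trial)
      worse <- f_try > f_cur
      if (!any(worse)) break
      step[worse] <- step[worse] / 2
    }
    improved <- f_try <= f_cur
    imp <- matrix(as.vector(improved), nf, np)
    Wc[2 * seq_len(nf) - 1, ] <- ifelse(imp, trial[2 * seq_len(nf) - 1, ],
                                        Wc[2 * seq_len(nf) - 1, ])
    Wc[2 * seq_len(nf), ] <- ifelse(imp, trial[2 * seq_len(nf), ],
                                    Wc[2 * seq_len(nf), ])
    if (max(abs(gx * as.numeric(imp)), abs(gy * as.numeric(imp))) < 1e-12) break
  }
  pick(anchor, Wc)
}

#' Update the auxiliary observations from the heightmaps
#'
#' For each frame/joint independently, minimizes
#' `-lambda5 * h_fp(w) + (mu/2) ||w - proj_fp||^2` where `proj_fp` is the
#' corresponding 2-vector of `R X# + E - Gamma1/mu`, by local gradient
#' descent on the interpolated surface seeded at `proj_fp` and at the
#' heightmap mode (keeping the better). The composite objective at the
#' result never exceeds its value at `proj_fp`; for a flat (uninformative)
#' heightmap the anchor itself is returned.
#'
#' @param stack a [heightmap_stack()].
#' @param Xsharp frame-wise motion matrix, 3NF x NP.
#' @param E,Gamma1 error and multiplier matrices, 2NF x NP.
#' @param mu positive penalty parameter.
#' @param lambda5 heightmap term weight.
#' @param cams a [camera_track()].
#' @return updated observations `What`, 2NF x NP (image units).
#' @export
update_What <- function(stack, Xsharp, E, Gamma1, mu, lambda5, cams) {
  if (mu <= 0) stop_input("'mu' must be > 0")
  anchor <- project_sharp(cams, Xsharp) + E - Gamma1 / mu
  update_what_core(stack, anchor, mu, lambda5)
}

#' Synthetic detector heightmaps
#'
#' Builds a heightmap stack that emulates a 2D joint detector on a known
#' scene: each grid carries an isotropic Gaussian bump (sd `sigma_px` pixels,
#' peak 1) at the true joint position, plus, when `clutter > 0`, a few
#' random smooth distractor bumps of amplitude `clutter`. The grid covers the
#' bounding box of all observations with a margin; deterministic given `seed`.
#'
#' @param W_true true observations, 2NF x NP (image units).
#' @param grid grid side length in pixels (square grids).
#' @param sigma_px Gaussian bump standard deviation, pixels.
#' @param clutter distractor amplitude in `[0, 1)`.
#' @param seed integer seed.
#' @return a [heightmap_stack()].
#' @export
synth_heightmaps <- function(W_true, grid = 64, sigma_px = 2, clutter = 0, seed = 1) {
  if (sigma_px <= 0) stop_input("'sigma_px' must be > 0")
  if (clutter < 0 || clutter >= 1) stop_input("'clutter' must lie in [0, 1)")
  nf <- nrow(W_true) %/% 2L
  np <- ncol(W_true)
  xs <- W_true[2 * seq_len(nf) - 1, , drop = FALSE]
  ys <- W_true[2 * seq_len(nf), , drop = FALSE]
  margin_px <- 6 * sigma_px
  rng <- max(max(xs) - min(xs), max(ys) - min(ys), .Machine$double.eps)
  scale <- (grid - 1 - 2 * margin_px) / rng
  if (scale <= 0) stop_input("grid too small for the requested margin")
  origin <- c(min(xs) - margin_px / scale, min(ys) - margin_px / scale)
  rowg <- seq_len(grid); colg <- seq_len(grid)
  maps <- array(0, dim = c(grid, grid, nf, np))
  withr::with_seed(seed, {
    for (p in seq_len(np)) {
      for (f in seq_len(nf)) {
        c0 <- (xs[f, p] - origin[1]) * scale + 1
        r0 <- (ys[f, p] - origin[2]) * scale + 1
        m <- exp(-(outer((rowg - r0)^2, (colg - c0)^2, "+")) / (2 * sigma_px^2))
        if (clutter > 0) {
          for (b in 1:2) {
            rc <- stats::runif(2, 1, grid)
            m <- m + clutter *
              exp(-(outer((rowg - rc[1])^2, (colg - rc[2])^2, "+")) / (2 * (2 * sigma_px)^2))
          }
        }
        maps[, , f, p] <- m
      }
    }
  })
  heightmap_stack(maps, origin = origin, scale = scale)
}

#' Marker-less reconstruction from heightmaps
#'
#' Runs the same ALM loop as [reconstruct()] with the observation matrix
#' replaced by the auxiliary variable `What`, re-estimated from the
#' heightmaps each outer iteration (after the `E` step) by [update_What()].
#' The coupling `W = What` is enforced by substitution. `What` is initialized
#' at the per-map heightmap modes; no per-frame centring is applied (the
#' heightmaps define absolute image coordinates).
#'
#' @param stack a [heightmap_stack()].
#' @param cams a [camera_track()].
#' @param skel a [skeleton()].
#' @param hyper a [tuns_params()] (`lambda5` weights the heightmap term).
#' @return a `tuns_fit` (see [reconstruct()]) with an extra element `What`:
#'   the final auxiliary observations in image units.
#' @export
reconstruct_markerless <- function(stack, cams, skel, hyper = tuns_params()) {
  if (stack$nf != n_frames(cams)) stop_input("heightmap stack and cameras disagree on NF")
  if (stack$np != skel$num_joints) stop_input("heightmap stack and skeleton disagree on NP")
  What0 <- stack$modes
  s <- sqrt(mean(What0^2))
  if (s <= 0) stop_input("degenerate heightmaps: zero-scale modes")
  updater <- function(state, cams) {
    anchor_img <- s * (project(cams, state$X) + state$E - state$Gamma1 / state$mu)
    update_what_core(stack, anchor_img, state$mu / s^2, hyper$lambda5) / s
  }
  state <- run_alm(What0 / s, cams, skel, hyper, what_updater = updater)
  structure(list(X = state$X * s, Z = state$Z, E = state$E * s,
                 l = state$l * s, C = state$C, converged = state$converged,
                 iterations = state$iter, residuals = state$residuals,
                 scale = s, centers = NULL, hyper = hyper,
                 kernel = state$kernel_resolved, What = state$W * s),
            class = "tuns_fit")
}

#' Read / write a heightmap stack
#'
#' On disk a stack is a directory with `maps.bin` (little-endian float32,
#' fastest-varying dimension first: row, column, frame, joint) and a JSON
#' sidecar `meta.json` with `h`, `w`, `nf`, `np`, `origin`, `scale`.
#'
#' @param dir directory path.
#' @return [read_heightmaps()] returns a [heightmap_stack()].
#' @export
read_heightmaps <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  n <- meta$h * meta$w * meta$nf * meta$np
  con <- file(file.path(dir, "maps.bin"), "rb")
  on.exit(close(con))
  vals <- readBin(con, what = "numeric", n = n, size = 4, endian = "little")
  maps <- array(vals, dim = c(meta$h, meta$w, meta$nf, meta$np))
  heightmap_stack(maps, origin = as.numeric(meta$origin), scale = meta$scale)
}

#' @rdname read_heightmaps
#' @param stack a [heightmap_stack()].
#' @export
write_heightmaps <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(dir, "maps.bin"), "wb")
  writeBin(as.vector(stack$maps), con, size = 4, endian = "little")
  close(con)
  jsonlite::write_json(list(h = stack$h, w = stack$w, nf = stack$nf,
                            np = stack$np, origin = stack$origin,
                            scale = stack$scale),
                       file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
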