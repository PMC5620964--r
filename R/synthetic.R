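# Forward-kinematics synthetic motion generator: articulated stick figures
# driven by smooth sinusoidal joint-angle trajectories, so bone lengths are
# conserved exactly and different action kinds occupy different nonlinear
# shape manifolds.

# preset tables: joint names, parent index (0 = root), rest offset from parent
skeleton_presets <- function() {
  stick13 <- list(
    names = c("pelvis", "thorax", "head",
              "lsho", "lelb", "lwri", "rsho", "relb", "rwri",
              "lkne", "lank", "rkne", "rank"),
    parent = c(0, 1, 2,
               2, 4, 5, 2, 7, 8,
               1, 10, 1, 12),
    offset = cbind(c(0, 0, 0),        # pelvis (root)
                   c(0, 0.45, 0),     # thorax
                   c(0, 0.25, 0),     # head
                   c(0.20, 0.05, 0),  # lsho
                   c(0.02, -0.28, 0), # lelb
                   c(0.01, -0.26, 0), # lwri
                   c(-0.20, 0.05, 0), # rsho
                   c(-0.02, -0.28, 0),# relb
                   c(-0.01, -0.26, 0),# rwri
                   c(0.12, -0.45, 0), # lkne
                   c(0.01, -0.45, 0), # lank
                   c(-0.12, -0.45, 0),# rkne
                   c(-0.01, -0.45, 0))# rank
  )
  stick15 <- list(
    names = c("pelvis", "thorax", "head",
              "lsho", "lelb", "lwri", "rsho", "relb", "rwri",
              "lhip", "lkne", "lank", "rhip", "rkne", "rank"),
    parent = c(0, 1, 2,
               2, 4, 5, 2, 7, 8,
               1, 10, 11, 1, 13, 14),
    offset = cbind(c(0, 0, 0),
                   c(0, 0.45, 0),
                   c(0, 0.25, 0),
                   c(0.20, 0.05, 0),
                   c(0.02, -0.28, 0),
                   c(0.01, -0.26, 0),
                   c(-0.20, 0.05, 0),
                   c(-0.02, -0.28, 0),
                   c(-0.01, -0.26, 0),
                   c(0.10, -0.06, 0),
                   c(0.02, -0.42, 0),
                   c(0.01, -0.44, 0),
                   c(-0.10, -0.06, 0),
                   c(-0.02, -0.42, 0),
                   c(-0.01, -0.44, 0))
  )
  list(stick13 = stick13, stick15 = stick15)
}

#' Stick-figure skeleton presets
#'
#' Builds a human stick-figure [skeleton()] (tree-structured bone graph) with
#' reference bone lengths, in body units where the figure stands about 1.7
#' units tall. `stick13` has 13 joints / 12 bones; `stick15` adds explicit
#' hip joints (15 joints / 14 bones).
#'
#' @param preset `"stick13"` or `"stick15"`.
#' @return a [skeleton()] carrying an extra attribute `fk` (parent/offset
#'   table used by the forward-kinematics generator).
#' @export
make_skeleton <- function(preset = c("stick13", "stick15")) {
  preset <- match.arg(preset)
  tb <- skeleton_presets()[[preset]]
  np <- length(tb$names)
  child <- which(tb$parent > 0)
  bones <- cbind(tb$parent[child], child)
  rest <- sqrt(colSums((tb$offset[, child, drop = FALSE])^2))
  sk <- skeleton(np, bones, names = tb$names, rest_lengths = rest)
  attr(sk, "fk") <- tb
  sk
}

rot_axis <- function(axis, angle) {
  c1 <- cos(angle); s1 <- sin(angle)
  switch(axis,
         x = matrix(c(1, 0, 0, 0, c1, s1, 0, -s1, c1), 3, 3),
         y = matrix(c(c1, 0, -s1, 0, 1, 0, s1, 0, c1), 3, 3),
         z = matrix(c(c1, s1, 0, -s1, c1, 0, 0, 0, 1), 3, 3))
}

# per-kind joint-angle programs: list of (joint name, axis, weight, phase0)
action_programs <- function(kind) {
  switch(kind,
    swing = list(
      list("lsho", "x", 1.0, 0), list("rsho", "x", -1.0, 0),
      list("lelb", "x", 0.4, 0.4), list("relb", "x", -0.4, 0.4),
      list("thorax", "y", 0.25, 0)
    ),
    walk_cycle = list(
      list("lkne", "x", 0.8, 0), list("rkne", "x", -0.8, 0),
      list("lank", "x", 0.5, 0.6), list("rank", "x", -0.5, 0.6),
      list("lsho", "x", -0.5, 0), list("rsho", "x", 0.5, 0),
      list("lelb", "x", -0.25, 0.3), list("relb", "x", 0.25, 0.3)
    ),
    reach = list(
      list("lsho", "z", 1.2, 0), list("lelb", "z", 0.35, 0.5),
      list("thorax", "z", 0.25, 0), list("head", "z", -0.2, 0.2),
      list("rsho", "x", 0.2, 0)
    ),
    crouch = list(
      list("lkne", "x", 0.9, 0), list("rkne", "x", 0.9, 0),
      list("lank", "x", -0.9, 0.1), list("rank", "x", -0.9, 0.1),
      list("thorax", "x", 0.5, 0), list("lsho", "x", 0.3, 0.2),
      list("rsho", "x", 0.3, 0.2)
    ),
    stop_input(sprintf("unknown action kind '%s'", kind))
  )
}

fk_pose <- function(tb, local_rot) {
  np <- length(tb$parent)
  pos <- matrix(0, 3, np)
  glob <- vector("list", np)
  for (j in seq_len(np)) {
    par <- tb$parent[j]
    if (par == 0) {
      glob[[j]] <- local_rot[[j]]
      pos[, j] <- c(0, 0, 0)
    } else {
      glob[[j]] <- glob[[par]] %*% local_rot[[j]]
      pos[, j] <- pos[, par] + glob[[par]] %*% tb$offset[, j]
    }
  }
  pos
}

#' Generate a primitive action by forward kinematics
#'
#' Produces per-frame 3D joint positions from the skeleton's rest pose with
#' smooth sinusoidal joint-angle trajectories; rotations applied at joints
#' preserve every bone length exactly (to machine precision) in every frame.
#' Each `kind` drives a different set of joints about different axes, so
#' different kinds trace different nonlinear shape manifolds. Small random
#' per-joint phase offsets (deterministic given `seed`) decorrelate repeated
#' calls.
#'
#' @param skel a skeleton from [make_skeleton()].
#' @param kind one of `"swing"`, `"walk_cycle"`, `"reach"`, `"crouch"`.
#' @param n_frames number of frames (>= 2).
#' @param amplitude peak joint-angle amplitude, radians (0 freezes the rest
#'   pose).
#' @param frequency number of action cycles over the clip.
#' @param seed integer seed for the phase offsets.
#' @return motion matrix X, 3NP x NF.
#' @export
generate_action <- function(skel, kind, n_frames, amplitude = 0.7,
                            frequency = 1, seed = 1) {
  tb <- attr(skel, "fk")
  if (is.null(tb)) stop_input("skeleton lacks forward-kinematics data; use make_skeleton()")
  if (n_frames < 2) stop_input("'n_frames' must be >= 2")
  prog <- action_programs(kind)
  np <- skel$num_joints
  phases <- withr::with_seed(seed, stats::runif(length(prog), -0.15, 0.15))
  X <- matrix(0, 3 * np, n_frames)
  for (f in seq_len(n_frames)) {
    t <- (f - 1) / n_frames
    local_rot <- rep(list(diag(3)), np)
    for (i in seq_along(prog)) {
      pr <- prog[[i]]
      j <- match(pr[[1]], skel$names)
      ang <- amplitude * pr[[3]] *
        sin(2 * pi * frequency * t + pr[[4]] + phases[i])
      local_rot[[j]] <- local_rot[[j]] %*% rot_axis(pr[[2]], ang)
    }
    X[, f] <- as.vector(fk_pose(tb, local_rot))
  }
  X
}

#' Concatenate action clips into a complex sequence
#'
#' Frame-wise concatenation of motion matrices sharing a skeleton, yielding
#' the union-of-subspaces structure of a "complex" motion. An optional linear
#' cross-fade of `fade` frames blends positions across each junction (this
#' slightly violates exact bone lengths inside the blended frames, so it is
#' off by default); labels follow the source clip.
#'
#' @param motions list of motion matrices with equal row counts.
#' @param labels optional integer label per clip (default `1..n`).
#' @param fade number of blended frames at each junction (0 disables).
#' @return list with `X` (concatenated motion) and `labels` (per-frame).
#' @export
concat_actions <- function(motions, labels = seq_along(motions), fade = 0) {
  if (!length(motions)) stop_input("need at least one motion")
  nr <- vapply(motions, nrow, integer(1))
  if (length(unique(nr)) != 1) stop_input("motions stem from different skeletons")
  X <- do.call(cbind, motions)
  lab <- rep(as.integer(labels), vapply(motions, ncol, integer(1)))
  if (fade > 0 && length(motions) > 1) {
    start <- cumsum(vapply(motions, ncol, integer(1)))
    for (j in start[-length(start)]) {
      prev <- X[, j]
      for (i in seq_len(min(fade, ncol(X) - j))) {
        w <- i / (fade + 1)
        X[, j + i] <- (1 - w) * prev + w * X[, j + i]
      }
    }
  }
  list(X = X, labels = lab)
}

#' Corrupt observations with noise and sparse outliers
#'
#' Adds i.i.d. Gaussian noise to every entry and replaces a fraction of the
#' (frame, joint) 2D observations with gross errors: a uniform offset of
#' magnitude between `0.5 * outlier_scale` and `outlier_scale` per coordinate
#' with random sign. Deterministic given `seed`; the indices of the corrupted
#' cells (column-major over the NF x NP cell grid) are attached as attribute
#' `outlier_cells`.
#'
#' @param W observation matrix, 2NF x NP.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param outlier_frac fraction of cells to corrupt, in `[0, 0.5]`.
#' @param outlier_scale magnitude of the gross errors.
#' @param seed integer seed.
#' @return corrupted observation matrix.
#' @export
corrupt_observations <- function(W, noise_sd = 0, outlier_frac = 0,
                                 outlier_scale = 1, seed = 1) {
  if (noise_sd < 0) stop_input("'noise_sd' must be >= 0")
  if (outlier_frac < 0 || outlier_frac > 0.5) stop_input("'outlier_frac' must lie in [0, 0.5]")
  nf <- nrow(W) %/% 2L
  np <- ncol(W)
  withr::with_seed(seed, {
    W2 <- W
    if (noise_sd > 0) W2 <- W2 + stats::rnorm(length(W2), sd = noise_sd)
    cells <- integer(0)
    n_out <- round(outlier_frac * nf * np)
    if (n_out > 0) {
      cells <- sort(sample.int(nf * np, n_out))
      for (cell in cells) {
        f <- (cell - 1) %% nf + 1
        p <- (cell - 1) %/% nf + 1
        delta <- outlier_scale * stats::runif(2, 0.5, 1) *
          sample(c(-1, 1), 2, replace = TRUE)
        W2[frame_rows2(f), p] <- W2[frame_rows2(f), p] + delta
      }
    }
    attr(W2, "outlier_cells") <- cells
    W2
  })
}

#' Generate a complete synthetic capture scene
#'
#' Builds a multi-action motion by forward kinematics, a camera rotating
#' about the vertical axis while pointing at the body, clean orthographic
#' projections, and optionally corrupted observations — everything needed to
#' exercise the full reconstruction pipeline offline.
#'
#' @param preset skeleton preset for [make_skeleton()].
#' @param actions character vector of action kinds.
#' @param n_frames integer vector of frames per action (recycled).
#' @param deg_per_frame camera rotation increment, degrees per frame.
#' @param noise_sd,outlier_frac,outlier_scale observation corruption, see
#'   [corrupt_observations()].
#' @param fade cross-fade frames at junctions (see [concat_actions()]).
#' @param seed integer seed driving action phases and corruption.
#' @return object of class `synthetic_scene`: `skeleton`, `X_gt`, `cams`,
#'   `W_clean`, `W_noisy`, `action_labels`, `outlier_cells`.
#' @export
make_scene <- function(preset = "stick13", actions = c("swing", "reach"),
                       n_frames = 60, deg_per_frame = 1.5, noise_sd = 0,
                       outlier_frac = 0, outlier_scale = 1, fade = 0,
                       seed = 7) {
  n_frames <- rep(as.integer(n_frames), length.out = length(actions))
  skel <- make_skeleton(preset)
  motions <- lapply(seq_along(actions), function(i) {
    generate_action(skel, actions[i], n_frames[i], seed = seed + i)
  })
  cc <- concat_actions(motions, fade = fade)
  cams <- make_rotating_camera(ncol(cc$X), deg_per_frame)
  W_clean <- project(cams, cc$X)
  W_noisy <- corrupt_observations(W_clean, noise_sd, outlier_frac,
                                  outlier_scale, seed = seed)
  structure(list(skeleton = skel, X_gt = cc$X, cams = cams,
                 W_clean = W_clean, W_noisy = W_noisy,
                 action_labels = cc$labels,
                 outlier_cells = attr(W_noisy, "outlier_cells")),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  d <- motion_dims(x$X_gt)
  cat(sprintf("<synthetic_scene: %d joints x %d frames, %d action(s)>\n",
              d$np, d$nf, length(unique(x$action_labels))))
  invisible(x)
}
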