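#' Orthographic camera track
#'
#' Bundles the per-frame 2x3 orthographic camera matrices `R_f`. Each matrix
#' must have orthonormal rows (`R_f R_f' = I_2` within `1e-8`). The stacked
#' block-diagonal matrix `R` (2NF x 3NF) projects the frame-wise motion matrix
#' `X#`: `W = R X#`.
#'
#' @param R either a `2 x 3 x NF` array, a list of 2x3 matrices, or a single
#'   2x3 matrix (one frame).
#' @return object of class `camera_track` (a `2 x 3 x NF` array).
#' @export
camera_track <- function(R) {
  if (is.list(R)) R <- array(unlist(R), dim = c(2, 3, length(R)))
  if (is.matrix(R)) R <- array(R, dim = c(2, 3, 1))
  if (!is.array(R) || length(dim(R)) != 3L || dim(R)[1] != 2L || dim(R)[2] != 3L) {
    stop_input("camera track must be a 2 x 3 x NF array or list of 2x3 matrices")
  }
  check_finite(R, "R")
  for (f in seq_len(dim(R)[3])) {
    gram <- R[, , f] %*% t(R[, , f])
    if (max(abs(gram - diag(2))) > 1e-8) {
      stop_input(sprintf("camera matrix for frame %d does not have orthonormal rows", f))
    }
  }
  structure(R, class = "camera_track")
}

#' @export
print.camera_track <- function(x, ...) {
  cat(sprintf("<camera_track: %d orthographic frames>\n", dim(x)[3]))
  invisible(x)
}

n_frames <- function(cams) dim(cams)[3]

#' Rearrange a motion matrix to frame-wise layout
#'
#' Converts the point-wise layout `X` (3NP x NF, column f stacks the NP
#' joint coordinates of frame f) into the frame-wise layout `X#`
#' (3NF x NP, row-block f holds frame f, column p is joint p). The two
#' layouts hold the same coordinates; `to_pointwise()` inverts the map.
#'
#' @param X motion matrix, 3NP x NF.
#' @return `X#`, a 3NF x NP matrix.
#' @export
to_framewise <- function(X) {
  X <- as.matrix(X)
  d <- motion_dims(X)
  arr <- array(X, dim = c(3, d$np, d$nf))
  matrix(aperm(arr, c(1, 3, 2)), nrow = 3 * d$nf, ncol = d$np)
}

#' @rdname to_framewise
#' @param Xsharp frame-wise motion matrix, 3NF x NP.
#' @export
to_pointwise <- function(Xsharp) {
  Xsharp <- as.matrix(Xsharp)
  if (nrow(Xsharp) %% 3L != 0L) stop_input("frame-wise matrix must have 3*NF rows")
  nf <- nrow(Xsharp) %/% 3L
  np <- ncol(Xsharp)
  arr <- array(Xsharp, dim = c(3, nf, np))
  matrix(aperm(arr, c(1, 3, 2)), nrow = 3 * np, ncol = nf)
}

#' Orthographic projection of a motion matrix
#'
#' Computes the observation matrix `W = R X#` (2NF x NP): rows `2f-1, 2f`
#' hold the two image coordinates of every joint at frame f.
#'
#' @param cams a [camera_track()] with NF frames.
#' @param X motion matrix, 3NP x NF (same NF).
#' @return W, 2NF x NP.
#' @export
project <- function(cams, X) {
  d <- motion_dims(X)
  if (n_frames(cams) != d$nf) stop_input("camera track and motion matrix disagree on NF")
  project_sharp(cams, to_framewise(X))
}

# W = R Xsharp without re-arranging (Xsharp is 3NF x NP)
project_sharp <- function(cams, Xsharp) {
  nf <- n_frames(cams)
  W <- matrix(0, 2 * nf, ncol(Xsharp))
  for (f in seq_len(nf)) {
    W[frame_rows2(f), ] <- cams[, , f] %*% Xsharp[frame_rows3(f), ]
  }
  W
}

# adjoint of X -> R X# in pointwise shape: G = (R' Q)# -> pointwise
backproject <- function(cams, Q) {
  nf <- n_frames(cams)
  Gs <- matrix(0, 3 * nf, ncol(Q))
  for (f in seq_len(nf)) {
    Gs[frame_rows3(f), ] <- t(cams[, , f]) %*% Q[frame_rows2(f), ]
  }
  to_pointwise(Gs)
}

#' Camera rotating about the vertical axis
#'
#' Builds a camera track whose frame-f matrix is the first two rows of a
#' rotation about the y (vertical) axis by `(f-1) * degrees_per_frame`,
#' emulating an orthographic camera that circles a body standing at the
#' origin while always pointing at its centre.
#'
#' @param NF number of frames (>= 1).
#' @param degrees_per_frame rotation increment, degrees.
#' @return a [camera_track()].
#' @export
make_rotating_camera <- function(NF, degrees_per_frame) {
  if (!is.numeric(NF) || length(NF) != 1L || is.na(NF) || NF < 1) {
    stop_input("'NF' must be a positive integer")
  }
  NF <- as.integer(NF)
  check_scalar(degrees_per_frame, "degrees_per_frame")
  ang <- (seq_len(NF) - 1) * degrees_per_frame * pi / 180
  R <- array(0, dim = c(2, 3, NF))
  R[1, 1, ] <- cos(ang)
  R[1, 3, ] <- sin(ang)
  R[2, 2, ] <- 1
  camera_track(R)
}
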