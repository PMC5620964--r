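#' Articulated skeleton
#'
#' A joint count and the set `B` of connected joint pairs (bones). Indices are
#' 1-based inside R; files use 0-based indices (see [read_skeleton()]).
#'
#' @param num_joints number of joints NP.
#' @param bones two-column matrix (or list of pairs) of joint indices, one row
#'   per bone; unordered duplicates are rejected.
#' @param names optional character vector of joint names.
#' @param rest_lengths optional positive reference bone lengths (one per bone).
#' @return object of class `skeleton`.
#' @export
skeleton <- function(num_joints, bones, names = NULL, rest_lengths = NULL) {
  if (is.list(bones)) bones <- do.call(rbind, bones)
  bones <- matrix(as.integer(bones), ncol = 2)
  np <- as.integer(num_joints)
  if (np < 1L) stop_input("'num_joints' must be >= 1")
  if (any(bones < 1L) || any(bones > np)) stop_input("bone indices out of 1..NP range")
  if (any(bones[, 1] == bones[, 2])) stop_input("a bone cannot connect a joint to itself")
  key <- paste(pmin(bones[, 1], bones[, 2]), pmax(bones[, 1], bones[, 2]))
  if (anyDuplicated(key)) stop_input("duplicate bones (unordered pairs) are not allowed")
  if (!is.null(names) && length(names) != np) stop_input("'names' must have one entry per joint")
  if (!is.null(rest_lengths)) {
    if (length(rest_lengths) != nrow(bones) || any(rest_lengths <= 0)) {
      stop_input("'rest_lengths' must be positive, one per bone")
    }
  }
  structure(list(num_joints = np, bones = bones, names = names,
                 rest_lengths = rest_lengths),
            class = "skeleton")
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("<skeleton: %d joints, %d bones>\n", x$num_joints, nrow(x$bones)))
  invisible(x)
}

# per-bone lengths for every frame: matrix nbones x NF
bone_lengths_by_frame <- function(X, skel) {
  d <- motion_dims(X)
  if (d$np != skel$num_joints) stop_input("motion matrix and skeleton disagree on NP")
  nb <- nrow(skel$bones)
  L <- matrix(0, nb, d$nf)
  for (b in seq_len(nb)) {
    D <- X[joint_rows(skel$bones[b, 1]), , drop = FALSE] -
      X[joint_rows(skel$bones[b, 2]), , drop = FALSE]
    L[b, ] <- sqrt(colSums(D * D))
  }
  L
}

#' Soft-inextensibility residual
#'
#' `R(X, l) = sum_f sum_(p,q) (||x_fp - x_fq|| - l_pq)^2` over the bone set:
#' zero exactly when every bone keeps its nominal length in every frame.
#'
#' @param X motion matrix, 3NP x NF.
#' @param l numeric vector of bone lengths, one per bone (order of
#'   `skel$bones`).
#' @param skel a [skeleton()].
#' @return nonnegative scalar.
#' @export
inext_residual <- function(X, l, skel) {
  if (length(l) != nrow(skel$bones) || anyNA(l)) {
    stop_input("'l' must supply one finite length per bone")
  }
  L <- bone_lengths_by_frame(X, skel)
  sum((L - l)^2)
}

#' Gradient of the inextensibility residual
#'
#' `dR/dx_fp = sum_(q:(p,q) in B) 2 (||d|| - l_pq) d / ||d||` with
#' `d = x_fp - x_fq` (mirrored for q). Undefined when two connected joints
#' coincide; such geometry raises an error.
#'
#' @inheritParams inext_residual
#' @return gradient matrix, same shape as `X`.
#' @export
inext_gradient <- function(X, l, skel) {
  if (length(l) != nrow(skel$bones) || anyNA(l)) {
    stop_input("'l' must supply one finite length per bone")
  }
  d <- motion_dims(X)
  if (d$np != skel$num_joints) stop_input("motion matrix and skeleton disagree on NP")
  G <- matrix(0, nrow(X), ncol(X))
  for (b in seq_len(nrow(skel$bones))) {
    p <- skel$bones[b, 1]; q <- skel$bones[b, 2]
    D <- X[joint_rows(p), , drop = FALSE] - X[joint_rows(q), , drop = FALSE]
    nd <- sqrt(colSums(D * D))
    if (any(nd <= 1e-9)) {
      stop_input(sprintf("degenerate geometry: joints %d and %d coincide in some frame", p, q))
    }
    coef <- 2 * (nd - l[b]) / nd
    Gb <- sweep(D, 2, coef, "*")
    G[joint_rows(p), ] <- G[joint_rows(p), ] + Gb
    G[joint_rows(q), ] <- G[joint_rows(q), ] - Gb
  }
  G
}

#' Closed-form bone-length update
#'
#' For fixed `X`, the residual `R(X, l)` is minimized per bone by the mean
#' over frames of the Euclidean bone length:
#' `l_pq = (1/NF) sum_f ||x_fp - x_fq||`.
#'
#' @inheritParams inext_residual
#' @return numeric vector of bone lengths (order of `skel$bones`).
#' @export
update_l <- function(X, skel) {
  rowMeans(bone_lengths_by_frame(X, skel))
}

#' Read / write a skeleton as JSON
#'
#' File schema: `num_joints` (integer), `bones` (list of 0-based index
#' pairs), optional `names` and `rest_lengths`. Indices are converted to
#' 1-based on read.
#'
#' @param path file path.
#' @return [read_skeleton()] returns a [skeleton()].
#' @export
read_skeleton <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$num_joints) || is.null(obj$bones)) {
    stop_input("skeleton file must contain 'num_joints' and 'bones'")
  }
  bones <- if (is.matrix(obj$bones)) {
    matrix(as.integer(obj$bones), ncol = 2)
  } else {
    matrix(as.integer(unlist(obj$bones)), ncol = 2, byrow = TRUE)
  }
  skeleton(obj$num_joints, bones + 1L, names = obj$names,
           rest_lengths = obj$rest_lengths)
}

#' @rdname read_skeleton
#' @param skel a [skeleton()].
#' @export
write_skeleton <- function(skel, path) {
  obj <- list(num_joints = skel$num_joints,
              bones = unname(skel$bones - 1L))
  if (!is.null(skel$names)) obj$names <- skel$names
  if (!is.null(skel$rest_lengths)) obj$rest_lengths <- skel$rest_lengths
  atomic_write(path, function(tmp) {
    jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA)
  })
  invisible(path)
}
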