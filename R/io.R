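# Delimited-text interchange: comma-separated, '.' decimal, UTF-8.
# All joint indices in files are 0-based; R-side objects are 1-based.

atomic_write <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop_input(sprintf("could not write '%s'", path))
  invisible(path)
}

read_numeric_table <- function(path, what) {
  if (!file.exists(path)) {
    stop_input(sprintf("%s file '%s' does not exist", what, path))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_input(sprintf("%s file '%s' is empty", what, path))
  first <- strsplit(lines[[1]], ",", fixed = TRUE)[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(first)))
  header <- if (has_header) trimws(first) else NULL
  body <- lines[(1 + has_header):length(lines)]
  rows <- lapply(seq_along(body), function(i) {
    vals <- suppressWarnings(as.numeric(strsplit(body[[i]], ",", fixed = TRUE)[[1]]))
    if (anyNA(vals)) {
      stop_input(sprintf("%s file '%s': non-numeric cell on line %d",
                         what, path, i + has_header))
    }
    vals
  })
  wid <- lengths(rows)
  if (length(unique(wid)) != 1) {
    stop_input(sprintf("%s file '%s': ragged rows (widths %s)", what, path,
                       paste(sort(unique(wid)), collapse = ", ")))
  }
  list(mat = do.call(rbind, rows), header = header)
}

write_csv_rows <- function(M, path, header = NULL) {
  atomic_write(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    if (!is.null(header)) writeLines(paste(header, collapse = ","), con)
    utils::write.table(format(M, digits = 17, trim = TRUE, scientific = TRUE),
                       con, sep = ",", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  })
}

#' Read / write 2D joint tracks
#'
#' Track file: NF rows and 2 NP columns (`x1, y1, x2, y2, ...`), optional
#' header row with joint names (`name_x, name_y` pairs). In memory tracks are
#' the observation matrix W (2NF x NP) with joint names as column names.
#'
#' @param path file path.
#' @return [read_tracks()] returns W, 2NF x NP.
#' @export
read_tracks <- function(path) {
  tb <- read_numeric_table(path, "track")
  M <- tb$mat
  if (ncol(M) %% 2L != 0L) {
    stop_input(sprintf("track file '%s' has %d columns; expected an even count",
                       path, ncol(M)))
  }
  nf <- nrow(M); np <- ncol(M) %/% 2L
  W <- matrix(0, 2 * nf, np)
  W[2 * seq_len(nf) - 1, ] <- M[, 2 * seq_len(np) - 1, drop = FALSE]
  W[2 * seq_len(nf), ] <- M[, 2 * seq_len(np), drop = FALSE]
  if (!is.null(tb$header)) {
    colnames(W) <- sub("_x$", "", tb$header[2 * seq_len(np) - 1])
  }
  W
}

#' @rdname read_tracks
#' @param W observation matrix, 2NF x NP (column names become joint names).
#' @export
write_tracks <- function(W, path) {
  nf <- nrow(W) %/% 2L; np <- ncol(W)
  M <- matrix(0, nf, 2 * np)
  M[, 2 * seq_len(np) - 1] <- W[2 * seq_len(nf) - 1, , drop = FALSE]
  M[, 2 * seq_len(np)] <- W[2 * seq_len(nf), , drop = FALSE]
  header <- NULL
  if (!is.null(colnames(W))) {
    header <- as.vector(rbind(paste0(colnames(W), "_x"), paste0(colnames(W), "_y")))
  }
  write_csv_rows(M, path, header)
}

#' Read / write camera rotations
#'
#' Rotation file: NF rows and 6 columns, the row-major entries of each 2x3
#' orthographic camera matrix.
#'
#' @param path file path.
#' @return [read_rotations()] returns a [camera_track()].
#' @export
read_rotations <- function(path) {
  tb <- read_numeric_table(path, "rotation")
  M <- tb$mat
  if (ncol(M) != 6L) {
    stop_input(sprintf("rotation file '%s' has %d columns; expected 6", path, ncol(M)))
  }
  R <- array(0, dim = c(2, 3, nrow(M)))
  for (f in seq_len(nrow(M))) {
    R[, , f] <- matrix(M[f, ], 2, 3, byrow = TRUE)
  }
  camera_track(R)
}

#' @rdname read_rotations
#' @param cams a [camera_track()].
#' @export
write_rotations <- function(cams, path) {
  nf <- dim(cams)[3]
  M <- t(vapply(seq_len(nf), function(f) as.vector(t(cams[, , f])), numeric(6)))
  write_csv_rows(M, path)
}

#' Read / write a 3D motion matrix
#'
#' Motion file: NF rows and 3 NP columns (`x, y, z` per joint), optional
#' header.
#'
#' @param path file path.
#' @return [read_motion()] returns X, 3NP x NF.
#' @export
read_motion <- function(path) {
  tb <- read_numeric_table(path, "motion")
  M <- tb$mat
  if (ncol(M) %% 3L != 0L) {
    stop_input(sprintf("motion file '%s' has %d columns; expected a multiple of 3",
                       path, ncol(M)))
  }
  t(M)  # NF x 3NP -> 3NP x NF; row f holds frame f's stacked joints
}

#' @rdname read_motion
#' @param X motion matrix, 3NP x NF.
#' @export
write_motion <- function(X, path) {
  write_csv_rows(t(X), path)
}

#' Read a run configuration
#'
#' YAML (or JSON) file whose keys mirror the [tuns_params()] arguments, with
#' the kernel given as a nested `kernel: {kind, bandwidth}` block. Missing
#' keys take the documented defaults; unknown keys raise an error (typo
#' protection); invalid values are reported together.
#'
#' @param path config file path, or `NULL` for all defaults.
#' @return a [tuns_params()].
#' @export
read_config <- function(path = NULL) {
  if (is.null(path)) return(tuns_params())
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  known <- setdiff(names(formals(tuns_params)), "")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop_input(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")))
  }
  if (!is.null(cfg$kernel)) {
    kb <- cfg$kernel
    cfg$kernel <- kernel_spec(kind = kb$kind %||% "rbf",
                              bandwidth = kb$bandwidth %||% "median",
                              median_scale = kb$median_scale %||% 0.5)
  }
  do.call(tuns_params, cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_config
#' @param params a [tuns_params()].
#' @export
write_config <- function(params, path) {
  out <- unclass(params)
  out$kernel <- list(kind = params$kernel$kind,
                     bandwidth = params$kernel$bandwidth,
                     median_scale = params$kernel$median_scale)
  atomic_write(path, function(tmp) yaml::write_yaml(out, tmp))
}
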