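#' Build a calibrated kymograph from an image stack
#'
#' Samples the stack along the axon path at `sampling_step` px intervals,
#' reducing intensities across a transverse window of `width` px (bilinear
#' interpolation at sub-pixel sample points). Rows are time (earliest first,
#' increasing downward); columns are arc length along the path, ordered so
#' that the column index increases toward the soma. Retrograde motion
#' therefore always drifts toward higher column indices — the orientation
#' contract on which the angle-based direction classification relies.
#'
#' @param stack An `image_stack`.
#' @param path An [axon_path()] ordered distal end -> soma end and lying
#'   inside the image bounds (including the transverse window).
#' @param reducer `"max"` (default; preserves dim puncta against background
#'   averaging) or `"mean"`.
#' @return An object of class `kymograph` with fields `matrix`
#'   (`n_frames x n_positions`), `row_scale` (s/row), `col_scale`
#'   (um/column) and `orientation` (`"soma_right"`).
#' @export
build_kymograph <- function(stack, path, reducer = c("max", "mean")) {
  reducer <- match.arg(reducer)
  stopifnot(inherits(stack, "image_stack"), inherits(path, "axon_path"))
  h <- nrow(stack$frames[[1]])
  w <- ncol(stack$frames[[1]])

  s <- seq(0, path$total_length, by = path$sampling_step)
  n_pos <- length(s)
  pts <- path_point(path, s)
  nrm <- path_normal(path, s)
  offsets <- seq(-(path$width - 1) / 2, (path$width - 1) / 2)
  # sample coordinates: n_pos x width, column-major flattened
  X <- outer(pts[, 1], rep(1, path$width)) +
    outer(nrm[, 1], offsets)
  Y <- outer(pts[, 2], rep(1, path$width)) +
    outer(nrm[, 2], offsets)
  bad <- which(X < 1 | X > w | Y < 1 | Y > h)
  if (length(bad)) {
    k <- (bad[1] - 1) %% n_pos + 1
    stop(sprintf(
      "axon path leaves the image: sample at arc %.1f px (x=%.1f, y=%.1f)",
      s[k], X[bad[1]], Y[bad[1]]), call. = FALSE)
  }
  # precompute bilinear interpolation indices/weights once
  x0 <- pmin(pmax(floor(X), 1), w - 1)
  y0 <- pmin(pmax(floor(Y), 1), h - 1)
  fx <- X - x0
  fy <- Y - y0
  i00 <- cbind(as.vector(y0), as.vector(x0))
  i01 <- cbind(as.vector(y0), as.vector(x0) + 1)
  i10 <- cbind(as.vector(y0) + 1, as.vector(x0))
  i11 <- cbind(as.vector(y0) + 1, as.vector(x0) + 1)
  w00 <- as.vector((1 - fx) * (1 - fy))
  w01 <- as.vector(fx * (1 - fy))
  w10 <- as.vector((1 - fx) * fy)
  w11 <- as.vector(fx * fy)

  n_frames <- length(stack$frames)
  K <- matrix(0, n_frames, n_pos)
  for (f in seq_len(n_frames)) {
    img <- stack$frames[[f]]
    v <- img[i00] * w00 + img[i01] * w01 + img[i10] * w10 + img[i11] * w11
    vm <- matrix(v, n_pos, path$width)
    K[f, ] <- if (reducer == "max") {
      do.call(pmax, as.data.frame(vm))
    } else {
      rowMeans(vm)
    }
  }
  structure(list(matrix = K,
                 row_scale = stack$acq$frame_interval,
                 col_scale = path$sampling_step * stack$acq$pixel_size,
                 orientation = "soma_right",
                 reducer = reducer, width = path$width),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf(
    "Kymograph: %d rows (%.3g s/row) x %d columns (%.3g um/col), soma at right\n",
    nrow(x$matrix), x$row_scale, ncol(x$matrix), x$col_scale))
  invisible(x)
}

#' Write a kymograph as a single-page TIFF with sidecar metadata
#'
#' @param kymo A `kymograph`.
#' @param path Output TIFF path; calibration (row_scale, col_scale,
#'   orientation, reducer) goes to `<path>.meta`.
#' @return `path`, invisibly.
#' @export
write_kymograph <- function(kymo, path) {
  stopifnot(inherits(kymo, "kymograph"))
  m <- round(pmax(kymo$matrix, 0))
  if (max(m) > 65535) m <- pmin(m, 65535)
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L,
                  compression = "none", reduce = FALSE)
  write_keyvalue(list(row_scale_s = kymo$row_scale,
                      col_scale_um = kymo$col_scale,
                      orientation = kymo$orientation,
                      reducer = kymo$reducer,
                      width_px = kymo$width),
                 paste0(path, ".meta"))
  invisible(path)
}

#' Read a kymograph written by [write_kymograph()]
#'
#' @param path TIFF path; requires the `<path>.meta` sidecar.
#' @return A `kymograph`.
#' @export
read_kymograph <- function(path) {
  meta_path <- paste0(path, ".meta")
  if (!file.exists(meta_path)) {
    stop("calibration sidecar missing (", meta_path, ")", call. = FALSE)
  }
  kv <- read_keyvalue(meta_path)
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  structure(list(matrix = round(m * 65535),
                 row_scale = kv_number(kv, "row_scale_s"),
                 col_scale = kv_number(kv, "col_scale_um"),
                 orientation = kv[["orientation"]] %||% "soma_right",
                 reducer = kv[["reducer"]] %||% "max",
                 width = kv_number(kv, "width_px", required = FALSE)),
            class = "kymograph")
}
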