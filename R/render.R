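#' Optical / camera settings for movie rendering
#'
#' @param psf_sigma Gaussian point-spread-function sigma in um (default 0.2,
#'   appropriate for far-red quantum-dot emission at high NA).
#' @param amplitude Peak spot intensity, photons/frame.
#' @param background Background level, photons/pixel/frame.
#' @param noise `"poisson"` for shot noise, `"none"` for deterministic
#'   rendering.
#' @param image_height,image_width Frame size in px. `image_width = NULL`
#'   sizes the frame to the axon path at render time.
#' @return An object of class `optics_config`.
#' @export
optics_config <- function(psf_sigma = 0.2, amplitude = 150, background = 5,
                          noise = c("poisson", "none"), image_height = 24,
                          image_width = NULL) {
  noise <- match.arg(noise)
  check_number(psf_sigma, "psf_sigma", lower = 0, strict_lower = TRUE)
  check_number(amplitude, "amplitude", lower = 0)
  check_number(background, "background", lower = 0)
  check_number(image_height, "image_height", lower = 1)
  if (!is.null(image_width)) check_number(image_width, "image_width", lower = 1)
  structure(list(psf_sigma = psf_sigma, amplitude = amplitude,
                 background = background, noise = noise,
                 image_height = as.integer(image_height),
                 image_width = if (is.null(image_width)) NULL
                               else as.integer(image_width)),
            class = "optics_config")
}

# Axon path --------------------------------------------------------------

#' Axon path (line ROI) in pixel coordinates
#'
#' A polyline ordered from the distal (axon-chamber) end to the soma end;
#' simulated positions (um from the distal end) are mapped onto its arc
#' length. Equivalent to an ImageJ segmented-line ROI.
#'
#' @param vertices Numeric matrix with columns (x, y) in pixel coordinates,
#'   at least two rows.
#' @param sampling_step Arc-length sampling step in px used when building
#'   kymographs (default 1).
#' @param width Transverse averaging window in px; odd, >= 1 (default 5).
#' @return An object of class `axon_path`.
#' @export
axon_path <- function(vertices, sampling_step = 1, width = 5) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 2 || ncol(vertices) != 2 || !is.numeric(vertices)) {
    stop("'vertices' must be a numeric matrix of >= 2 (x, y) rows",
         call. = FALSE)
  }
  check_number(sampling_step, "sampling_step", lower = 0, strict_lower = TRUE)
  if (width < 1 || width %% 2 != 1) {
    stop("'width' must be an odd integer >= 1", call. = FALSE)
  }
  d <- diff(vertices)
  seg_len <- sqrt(rowSums(d^2))
  if (any(seg_len == 0)) stop("degenerate (zero-length) path segment",
                              call. = FALSE)
  structure(list(vertices = vertices, sampling_step = sampling_step,
                 width = as.integer(width), seg_len = seg_len,
                 cum_len = c(0, cumsum(seg_len)),
                 total_length = sum(seg_len)),
            class = "axon_path")
}

#' Straight horizontal axon path
#'
#' Default geometry for axons in microfluidic microgrooves: a straight
#' horizontal line starting `margin_px` from the left image edge.
#'
#' @param axon_length_um Axon length in um.
#' @param pixel_size um per px.
#' @param y Row coordinate of the axon (px).
#' @param margin_px Margin before the distal end (px).
#' @inheritParams axon_path
#' @return An `axon_path`.
#' @export
straight_axon_path <- function(axon_length_um, pixel_size, y = 12,
                               margin_px = 8, sampling_step = 1, width = 5) {
  x1 <- margin_px + axon_length_um / pixel_size
  axon_path(rbind(c(margin_px, y), c(x1, y)),
            sampling_step = sampling_step, width = width)
}

# Interpolate points at arc lengths s (px) along the path.
path_point <- function(path, s) {
  if (any(s < -1e-6 | s > path$total_length + 1e-6)) {
    stop("arc length outside the axon path", call. = FALSE)
  }
  s <- pmin(pmax(s, 0), path$total_length)
  idx <- findInterval(s, path$cum_len, rightmost.closed = TRUE,
                      all.inside = TRUE)
  frac <- (s - path$cum_len[idx]) / path$seg_len[idx]
  p0 <- path$vertices[idx, , drop = FALSE]
  p1 <- path$vertices[idx + 1, , drop = FALSE]
  p0 + frac * (p1 - p0)
}

# Unit normals of the path segments containing arc lengths s.
path_normal <- function(path, s) {
  s <- pmin(pmax(s, 0), path$total_length)
  idx <- findInterval(s, path$cum_len, rightmost.closed = TRUE,
                      all.inside = TRUE)
  d <- diff(path$vertices)
  t_hat <- d / path$seg_len
  cbind(-t_hat[idx, 2], t_hat[idx, 1])
}

# Rendering --------------------------------------------------------------

add_spot <- function(img, x, y, amplitude, sigma_px, radius_px) {
  h <- nrow(img)
  w <- ncol(img)
  jx <- max(1L, floor(x - radius_px)):min(w, ceiling(x + radius_px))
  iy <- max(1L, floor(y - radius_px)):min(h, ceiling(y + radius_px))
  if (!length(jx) || !length(iy)) return(img)
  gx <- exp(-((jx - x)^2) / (2 * sigma_px^2))
  gy <- exp(-((iy - y)^2) / (2 * sigma_px^2))
  img[iy, jx] <- img[iy, jx] + amplitude * outer(gy, gx)
  img
}

#' Render trajectories into a microscope-like image stack
#'
#' Each cargo is drawn as an isotropic Gaussian spot centred at its
#' sub-pixel position mapped onto the axon path; the Gaussian is truncated
#' at 4 sigma (< 0.01% mass loss). Optional Poisson shot noise is applied
#' per pixel. Rendering is deterministic given `seed`.
#'
#' @param trajectories A `trajectory`, a list of them, or a
#'   `transport_cohort`.
#' @param path An [axon_path()]; 1-D positions (um) are mapped to arc length
#'   `position / pixel_size` (px) from the first vertex.
#' @param acq The [acquisition_config()].
#' @param optics An [optics_config()].
#' @param seed Integer seed (used only when `noise = "poisson"`).
#' @return An object of class `image_stack`: list of `n_frames` matrices
#'   (rows = y) plus acquisition/optics metadata.
#' @export
render_stack <- function(trajectories, path, acq, optics = optics_config(),
                         seed = 1) {
  if (inherits(trajectories, "transport_cohort")) {
    trajectories <- trajectories$trajectories
  }
  if (inherits(trajectories, "trajectory")) trajectories <- list(trajectories)
  stopifnot(length(trajectories) >= 1, inherits(path, "axon_path"),
            inherits(acq, "acquisition_config"),
            inherits(optics, "optics_config"))
  n <- acq$n_frames
  h <- optics$image_height
  w <- optics$image_width %||%
    as.integer(ceiling(max(path$vertices[, 1])) + 8L)
  sigma_px <- optics$psf_sigma / acq$pixel_size
  radius_px <- max(1, ceiling(4 * sigma_px))

  coords <- vector("list", length(trajectories))
  for (ti in seq_along(trajectories)) {
    tr <- trajectories[[ti]]
    stopifnot(inherits(tr, "trajectory"))
    if (length(tr$positions) != n) {
      stop("trajectory ", ti, " has ", length(tr$positions),
           " frames; acquisition expects ", n, call. = FALSE)
    }
    s <- tr$positions / acq$pixel_size
    bad <- which(s < -1e-6 | s > path$total_length + 1e-6)
    if (length(bad)) {
      stop(sprintf("track %s frame %d: position %.2f um is off the axon path",
                   tr$track_id %||% as.character(ti), bad[1],
                   tr$positions[bad[1]]), call. = FALSE)
    }
    coords[[ti]] <- path_point(path, s)
  }

  frames <- vector("list", n)
  run_seeded(seed, {
    for (f in seq_len(n)) {
      img <- matrix(optics$background, h, w)
      for (ti in seq_along(coords)) {
        img <- add_spot(img, coords[[ti]][f, 1], coords[[ti]][f, 2],
                        optics$amplitude, sigma_px, radius_px)
      }
      if (optics$noise == "poisson") {
        img <- matrix(stats::rpois(length(img), as.vector(img)), h, w)
      }
      frames[[f]] <- img
    }
  })
  structure(list(frames = frames, acq = acq, optics = optics),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("Image stack: %d frames of %d x %d px (%.3g um/px, %.3g s/frame)\n",
              length(x$frames), nrow(x$frames[[1]]), ncol(x$frames[[1]]),
              x$acq$pixel_size, x$acq$frame_interval))
  invisible(x)
}

# Stack I/O ---------------------------------------------------------------

#' Write an image stack as a calibrated multi-page TIFF
#'
#' Intensities are rounded to integer photon counts and stored as 16-bit
#' unsigned samples, one page per frame. Calibration (pixel size, frame
#' interval) is written to a plain-text sidecar `<path>.meta` with key=value
#' lines; [read_stack()] refuses to read a stack without it.
#'
#' @param stack An `image_stack`.
#' @param path Output TIFF path.
#' @param extra_meta Optional named list of extra metadata values to store.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, extra_meta = list()) {
  stopifnot(inherits(stack, "image_stack"))
  counts <- lapply(stack$frames, function(f) round(pmax(f, 0)))
  mx <- max(vapply(counts, max, numeric(1)))
  if (mx > 65535) {
    warning("intensities above 65535 clipped on 16-bit write")
    counts <- lapply(counts, function(f) pmin(f, 65535))
  }
  tiff::writeTIFF(lapply(counts, function(f) f / 65535), path,
                  bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  meta <- c(list(pixel_size_um = stack$acq$pixel_size,
                 frame_interval_s = stack$acq$frame_interval,
                 duration_s = stack$acq$duration,
                 n_frames = length(stack$frames),
                 psf_sigma_um = stack$optics$psf_sigma),
            extra_meta)
  write_keyvalue(meta, paste0(path, ".meta"))
  invisible(path)
}

#' Read a calibrated multi-page TIFF stack
#'
#' Requires the `<path>.meta` sidecar written by [write_stack()]; a missing
#' or incomplete sidecar is an error (calibration is never silently
#' defaulted).
#'
#' @param path TIFF path.
#' @return An `image_stack`; extra sidecar keys are attached as the `meta`
#'   field.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  meta_path <- paste0(path, ".meta")
  if (!file.exists(meta_path)) {
    stop("calibration sidecar missing (", meta_path,
         "): refusing to read an uncalibrated stack", call. = FALSE)
  }
  kv <- read_keyvalue(meta_path)
  pixel_size <- kv_number(kv, "pixel_size_um")
  frame_interval <- kv_number(kv, "frame_interval_s")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]
    round(p * 65535)
  })
  acq <- acquisition_config(frame_interval = frame_interval,
                            duration = frame_interval * length(frames),
                            pixel_size = pixel_size)
  psf <- kv_number(kv, "psf_sigma_um", required = FALSE) %||% 0.2
  optics <- optics_config(psf_sigma = psf, noise = "none",
                          image_height = nrow(frames[[1]]),
                          image_width = ncol(frames[[1]]))
  structure(list(frames = frames, acq = acq, optics = optics, meta = kv),
            class = "image_stack")
}
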