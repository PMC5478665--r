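#' Detect particles in every kymograph row
#'
#' Finds local intensity maxima along each row (time point) that exceed the
#' row background (median) by `min_snr` robust standard deviations (MAD),
#' then refines each peak to sub-pixel precision by three-point parabolic
#' interpolation.
#'
#' @param kymo A `kymograph`.
#' @param min_snr Detection threshold in MADs above the row median.
#' @return Data frame with columns `frame`, `position` (sub-pixel column,
#'   1-based) and `intensity`; zero rows if nothing is detected.
#' @export
detect_per_frame <- function(kymo, min_snr = 3) {
  stopifnot(inherits(kymo, "kymograph"), nrow(kymo$matrix) >= 1)
  check_number(min_snr, "min_snr", lower = 0)
  M <- kymo$matrix
  n <- ncol(M)
  out <- vector("list", nrow(M))
  for (f in seq_len(nrow(M))) {
    row <- M[f, ]
    th <- stats::median(row) + min_snr * stats::mad(row)
    left <- c(-Inf, row[-n])
    right <- c(row[-1], -Inf)
    pk <- which(row > th & row > left & row >= right)
    if (!length(pk)) next
    pos <- as.numeric(pk)
    inner <- pk > 1 & pk < n
    if (any(inner)) {
      i <- pk[inner]
      denom <- row[i - 1] - 2 * row[i] + row[i + 1]
      dx <- ifelse(denom < 0, 0.5 * (row[i - 1] - row[i + 1]) / denom, 0)
      pos[inner] <- i + pmin(pmax(dx, -0.5), 0.5)
    }
    out[[f]] <- data.frame(frame = f, position = pos, intensity = row[pk])
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(frame = integer(0), position = numeric(0),
                      intensity = numeric(0)))
  }
  do.call(rbind, out)
}

#' Link per-frame detections into tracks
#'
#' Greedy nearest-neighbour frame-to-frame linking: at each frame,
#' candidate (track, detection) pairs within `max_jump` um per elapsed
#' frame are assigned in order of increasing distance; unmatched detections
#' open new tracks. Detection dropouts up to `max_gap` frames are bridged
#' by linear interpolation of position. Tracks spanning fewer than
#' `min_track_len` frames are discarded.
#'
#' @param detections Data frame from [detect_per_frame()].
#' @param kymo The `kymograph` the detections came from (for calibration).
#' @param max_jump Maximum allowed displacement, um per frame.
#' @param max_gap Maximum bridged detection gap, frames.
#' @param min_track_len Minimum track span, frames.
#' @return List of `cargo_track` objects.
#' @export
link_tracks <- function(detections, kymo, max_jump = 2, max_gap = 3,
                        min_track_len = 10) {
  stopifnot(inherits(kymo, "kymograph"))
  check_number(max_jump, "max_jump", lower = 0, strict_lower = TRUE)
  jump_cols <- max_jump / kymo$col_scale
  tracks <- list()
  last_frame <- integer(0)
  last_pos <- numeric(0)

  for (f in sort(unique(detections$frame))) {
    dets <- detections[detections$frame == f, , drop = FALSE]
    open <- which(last_frame >= f - (max_gap + 1L) & last_frame < f)
    assigned_det <- rep(FALSE, nrow(dets))
    assigned_trk <- rep(FALSE, length(open))
    if (length(open) && nrow(dets)) {
      gap <- f - last_frame[open]
      cost <- abs(outer(dets$position, last_pos[open], "-"))
      gate <- sweep(cost, 2, jump_cols * gap, "<=")
      ord <- order(cost)
      for (idx in ord) {
        di <- (idx - 1) %% nrow(dets) + 1
        tj <- (idx - 1) %/% nrow(dets) + 1
        if (!gate[di, tj] || assigned_det[di] || assigned_trk[tj]) next
        ti <- open[tj]
        tracks[[ti]]$frame <- c(tracks[[ti]]$frame, f)
        tracks[[ti]]$pos <- c(tracks[[ti]]$pos, dets$position[di])
        last_frame[ti] <- f
        last_pos[ti] <- dets$position[di]
        assigned_det[di] <- TRUE
        assigned_trk[tj] <- TRUE
      }
    }
    for (di in which(!assigned_det)) {
      tracks[[length(tracks) + 1L]] <- list(frame = f,
                                            pos = dets$position[di])
      last_frame <- c(last_frame, f)
      last_pos <- c(last_pos, dets$position[di])
    }
  }

  out <- list()
  for (tr in tracks) {
    span <- tr$frame[length(tr$frame)] - tr$frame[1] + 1L
    if (span < min_track_len) next
    full <- tr$frame[1]:tr$frame[length(tr$frame)]
    pos <- stats::approx(tr$frame, tr$pos, xout = full)$y
    out[[length(out) + 1L]] <- cargo_track(
      frame = full, position_um = (pos - 1) * kymo$col_scale,
      row_scale = kymo$row_scale, col_scale = kymo$col_scale,
      track_id = sprintf("track_%03d", length(out) + 1L),
      interpolated = !(full %in% tr$frame),
      position_col = pos)
  }
  out
}

#' Construct a cargo track
#'
#' The pipeline's representation of one traced particle: positions in um
#' along the axon (soma-ward increasing) on consecutive frames.
#'
#' @param frame Integer vector of consecutive frame indices.
#' @param position_um Positions in um (same length as `frame`).
#' @param row_scale Seconds per frame.
#' @param col_scale um per kymograph column (NA if not image-derived).
#' @param track_id Identifier string.
#' @param group Optional group label.
#' @param interpolated Logical vector flagging gap-bridged frames.
#' @param position_col Optional raw sub-pixel column positions.
#' @return An object of class `cargo_track`.
#' @export
cargo_track <- function(frame, position_um, row_scale = 1, col_scale = NA,
                        track_id = "track_001", group = NA_character_,
                        interpolated = NULL, position_col = NULL) {
  frame <- as.integer(frame)
  if (length(frame) < 2 || any(diff(frame) != 1L)) {
    stop("'frame' must be >= 2 consecutive integers", call. = FALSE)
  }
  stopifnot(length(position_um) == length(frame))
  structure(list(frame = frame,
                 time_s = (frame - 1) * row_scale,
                 position_um = as.numeric(position_um),
                 interpolated = interpolated %||% rep(FALSE, length(frame)),
                 position_col = position_col,
                 row_scale = row_scale, col_scale = col_scale,
                 track_id = track_id, group = group),
            class = "cargo_track")
}

#' @export
print.cargo_track <- function(x, ...) {
  cat(sprintf("Cargo track %s: frames %d-%d, %.1f -> %.1f um\n",
              x$track_id, x$frame[1], x$frame[length(x$frame)],
              x$position_um[1], x$position_um[length(x$position_um)]))
  invisible(x)
}

#' Convert a simulated trajectory to a pipeline track
#'
#' The "from-tracks" route: wraps ground-truth positions as a `cargo_track`
#' so the segmentation/metrics stages can run without the imaging chain.
#'
#' @param traj A `trajectory`.
#' @return A `cargo_track`.
#' @export
trajectory_to_track <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  cargo_track(frame = seq_along(traj$positions),
              position_um = traj$positions,
              row_scale = traj$acq$frame_interval,
              col_scale = traj$acq$pixel_size,
              track_id = traj$track_id %||% "track_001",
              group = traj$group %||% NA_character_)
}

#' Segment a track into runs and pauses
#'
#' Labels every inter-frame step `stationary` when its absolute
#' displacement is below `delta`, otherwise `retrograde` (soma-ward,
#' positive) or `anterograde` by sign, then merges consecutive same-label
#' steps into maximal segments. Segments tile the track exactly: segment
#' durations sum to the track duration with no overlaps.
#'
#' @param track A `cargo_track` with >= 2 frames.
#' @param delta Stationarity threshold, um per frame (> 0). Default 0.1 um
#'   (half the default PSF sigma): sub-resolution jitter must not break
#'   pauses.
#' @return An object of class `track_segments`: a data frame with columns
#'   `class`, `start_frame`, `end_frame`, `start_pos`, `end_pos`,
#'   `duration` (s) and `u` (signed soma-ward displacement, um), with the
#'   track id, total time and `delta` attached as attributes.
#' @export
segment_track <- function(track, delta = 0.1) {
  stopifnot(inherits(track, "cargo_track"))
  if (!is.numeric(delta) || length(delta) != 1 || !is.finite(delta) ||
      delta <= 0) {
    stop("'delta' must be a single positive number", call. = FALSE)
  }
  p <- track$position_um
  d <- diff(p)
  cls <- ifelse(abs(d) < delta, "stationary",
                ifelse(d > 0, "retrograde", "anterograde"))
  r <- rle(cls)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- data.frame(class = r$values,
                    start_frame = track$frame[starts],
                    end_frame = track$frame[ends + 1L],
                    start_pos = p[starts],
                    end_pos = p[ends + 1L],
                    duration = r$lengths * track$row_scale,
                    u = p[ends + 1L] - p[starts],
                    stringsAsFactors = FALSE)
  structure(seg, class = c("track_segments", "data.frame"),
            track_id = track$track_id, group = track$group,
            total_time = (length(p) - 1) * track$row_scale,
            row_scale = track$row_scale,
            col_scale = track$col_scale, delta = delta)
}

#' Per-step class labels implied by a segmentation
#'
#' Expands segments back to one label per inter-frame step, for comparison
#' with simulator ground-truth states.
#'
#' @param segments A `track_segments`.
#' @return Character vector, one label per step.
#' @export
segment_step_labels <- function(segments) {
  stopifnot(inherits(segments, "track_segments"))
  rep(segments$class, segments$end_frame - segments$start_frame)
}
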