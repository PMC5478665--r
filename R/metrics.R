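#' Angle cut-offs for kymograph direction classification
#'
#' The standard cut-offs used to classify each kymograph line by its angle:
#' retrograde for angles in `[-89.4, -1]` degrees, anterograde below
#' `-90.6`, stationary within `0.5` degrees of `-90` (a vertical line, i.e.
#' time passing with no displacement). The two 0.1-degree-wide slivers the
#' printed cut-offs leave open, `(-89.5, -89.4)` and `(-90.6, -90.5)`, are
#' closed into the stationary class; angles above `-1` (a near-instantaneous
#' jump) are reported as `unclassified` with a warning and excluded from
#' metrics.
#'
#' @param retro_lo,retro_hi Retrograde band, degrees.
#' @param antero_max Anterograde upper bound, degrees.
#' @param stationary_halfwidth Half-width of the stationary band about -90.
#' @return An object of class `angle_cutoffs`.
#' @export
angle_cutoffs <- function(retro_lo = -89.4, retro_hi = -1,
                          antero_max = -90.6, stationary_halfwidth = 0.5) {
  if (!(antero_max < -90 && -90 < retro_lo && retro_lo < retro_hi &&
        retro_hi < 0)) {
    stop("cut-offs must satisfy antero_max < -90 < retro_lo < retro_hi < 0",
         call. = FALSE)
  }
  check_number(stationary_halfwidth, "stationary_halfwidth", lower = 0)
  structure(list(retro_lo = retro_lo, retro_hi = retro_hi,
                 antero_max = antero_max,
                 stationary_halfwidth = stationary_halfwidth),
            class = "angle_cutoffs")
}

#' Kymograph angle of a track segment
#'
#' The angle of the line a segment draws on the kymograph, measured with
#' time increasing downward and the soma to the right:
#' `theta = -atan2(duration / row_scale, u / col_scale)` in degrees, where
#' `u` is the signed soma-ward displacement. Since duration is positive,
#' `theta` lies in `(-180, 0)`: retrograde segments fall in `(-90, 0)`,
#' anterograde in `(-180, -90)`, and zero displacement gives exactly `-90`.
#'
#' @param u Signed soma-ward displacement, um (vectorised).
#' @param duration Segment duration, s (> 0; vectorised).
#' @param row_scale Seconds per kymograph row.
#' @param col_scale um per kymograph column.
#' @return Angle(s) in degrees.
#' @export
segment_angle <- function(u, duration, row_scale = 1, col_scale = 1) {
  if (any(!is.finite(duration)) || any(duration <= 0)) {
    stop("segment duration must be positive", call. = FALSE)
  }
  -atan2(duration / row_scale, u / col_scale) * 180 / pi
}

#' Classify kymograph angles into transport direction classes
#'
#' @param theta Angle(s) in degrees, inside the open interval `(-180, 0)`.
#' @param cutoffs An [angle_cutoffs()] object.
#' @return Character vector: `"retrograde"`, `"anterograde"`,
#'   `"stationary"` or `"unclassified"` (with a warning).
#' @export
classify_angle <- function(theta, cutoffs = angle_cutoffs()) {
  stopifnot(inherits(cutoffs, "angle_cutoffs"))
  if (any(!is.finite(theta)) || any(theta <= -180) || any(theta >= 0)) {
    stop("angle outside the kymograph domain (-180, 0) degrees",
         call. = FALSE)
  }
  out <- character(length(theta))
  stationary <- abs(theta + 90) <= cutoffs$stationary_halfwidth
  retro <- !stationary & theta >= cutoffs$retro_lo & theta <= cutoffs$retro_hi
  antero <- !stationary & theta <= cutoffs$antero_max
  unclass_ <- !stationary & !retro & !antero & theta > cutoffs$retro_hi
  gap <- !(stationary | retro | antero | unclass_)
  out[stationary | gap] <- "stationary"
  out[retro] <- "retrograde"
  out[antero] <- "anterograde"
  out[unclass_] <- "unclassified"
  if (any(unclass_)) {
    warning(sprintf(
      "%d angle(s) above %.1f deg (near-instantaneous jumps) left unclassified",
      sum(unclass_), cutoffs$retro_hi))
  }
  out
}

#' Annotate segments with kymograph angles and angle-based classes
#'
#' @param segments A `track_segments` object.
#' @param cutoffs An [angle_cutoffs()].
#' @return The segments with `theta` and `angle_class` columns added.
#' @export
annotate_angles <- function(segments, cutoffs = angle_cutoffs()) {
  stopifnot(inherits(segments, "track_segments"))
  rs <- attr(segments, "row_scale") %||% 1
  cs <- attr(segments, "col_scale")
  if (is.null(cs) || is.na(cs)) cs <- 1
  segments$theta <- segment_angle(segments$u, segments$duration, rs, cs)
  segments$angle_class <- classify_angle(segments$theta, cutoffs)
  segments
}

#' Per-cargo transport metrics
#'
#' Computes the standard per-cargo statistics from a track's segments:
#' distance is the cumulative path length over non-stationary segments
#' (`distance_mode = "net"` uses |net displacement| instead); pause time is
#' the summed duration of stationary segments; average velocity is
#' distance over total time (pauses included); moving velocity is distance
#' over moving time (total minus pause), defined as 0 for a cargo that
#' never moves; pause percentage is pause time over total time x 100.
#'
#' @param segments A `track_segments` object (optionally angle-annotated;
#'   `angle_class == "unclassified"` segments are excluded from the
#'   distance with a warning).
#' @param total_time Total observation time, s; defaults to the summed
#'   segment durations.
#' @param distance_mode `"path"` (default) or `"net"`.
#' @return Object of class `transport_metrics`: a list with `distance`,
#'   `total_time`, `pause_time`, `average_velocity`, `moving_velocity`,
#'   `pause_percent`, `n_pause_events` and per-class segment counts.
#' @export
track_metrics <- function(segments, total_time = NULL,
                          distance_mode = c("path", "net")) {
  distance_mode <- match.arg(distance_mode)
  stopifnot(inherits(segments, "track_segments"))
  total_time <- total_time %||% attr(segments, "total_time") %||%
    sum(segments$duration)
  if (!is.numeric(total_time) || total_time <= 0) {
    stop("'total_time' must be positive", call. = FALSE)
  }
  cls <- segments$angle_class %||% segments$class
  keep <- cls != "unclassified"
  if (!all(keep)) {
    warning(sum(!keep), " unclassified segment(s) excluded from metrics")
  }
  seg <- segments[keep, , drop = FALSE]
  cls <- cls[keep]
  moving <- cls != "stationary"
  distance <- if (distance_mode == "path") sum(abs(seg$u[moving]))
              else abs(sum(seg$u[moving]))
  pause_time <- sum(seg$duration[!moving])
  if (pause_time > total_time + 1e-9) {
    stop("pause time exceeds total time", call. = FALSE)
  }
  if (distance > 0 && total_time - pause_time <= 0) {
    stop("impossible state: positive distance with zero moving time",
         call. = FALSE)
  }
  moving_velocity <- if (distance == 0) 0 else distance / (total_time - pause_time)
  structure(list(
    distance = distance,
    total_time = total_time,
    pause_time = pause_time,
    average_velocity = distance / total_time,
    moving_velocity = moving_velocity,
    pause_percent = 100 * pause_time / total_time,
    n_pause_events = sum(!moving),
    n_retrograde_segments = sum(cls == "retrograde"),
    n_anterograde_segments = sum(cls == "anterograde"),
    track_id = attr(segments, "track_id"),
    group = attr(segments, "group"),
    distance_mode = distance_mode),
    class = "transport_metrics")
}

#' @export
print.transport_metrics <- function(x, ...) {
  cat(sprintf(paste0(
    "Transport metrics (%s): distance %.2f um in %.4g s\n",
    "  average %.3f um/s, moving %.3f um/s, pause %.1f%% (%d event(s))\n"),
    x$track_id %||% "track", x$distance, x$total_time,
    x$average_velocity, x$moving_velocity, x$pause_percent,
    x$n_pause_events))
  invisible(x)
}

#' @export
as.data.frame.transport_metrics <- function(x, ...) {
  data.frame(track_id = x$track_id %||% NA_character_,
             group = x$group %||% NA_character_,
             distance = x$distance, total_time = x$total_time,
             pause_time = x$pause_time,
             average_velocity = x$average_velocity,
             moving_velocity = x$moving_velocity,
             pause_percent = x$pause_percent,
             n_pause_events = x$n_pause_events,
             n_retrograde_segments = x$n_retrograde_segments,
             n_anterograde_segments = x$n_anterograde_segments,
             stringsAsFactors = FALSE)
}

#' Segment and measure a list of tracks
#'
#' Convenience chain: [segment_track()] then [track_metrics()] for each
#' track, returning a tidy per-track table.
#'
#' @param tracks List of `cargo_track` objects.
#' @param delta Stationarity threshold passed to [segment_track()].
#' @param distance_mode Passed to [track_metrics()].
#' @return Data frame, one row per track.
#' @export
analyze_tracks <- function(tracks, delta = 0.1,
                           distance_mode = c("path", "net")) {
  distance_mode <- match.arg(distance_mode)
  stopifnot(length(tracks) >= 1)
  do.call(rbind, lapply(tracks, function(tr) {
    as.data.frame(track_metrics(segment_track(tr, delta = delta),
                                distance_mode = distance_mode))
  }))
}

#' Per-group summary of transport metrics
#'
#' @param metrics Data frame from [analyze_tracks()] (columns `group`,
#'   `moving_velocity`, `average_velocity`, `pause_percent`).
#' @param variables Metric columns to summarise.
#' @return List with `per_track` (the input) and `summary`: one row per
#'   group and variable with `n`, `mean` and `sem` (0 with `n_flag = 1`
#'   for singleton groups).
#' @export
cohort_metrics <- function(metrics,
                           variables = c("moving_velocity",
                                         "average_velocity",
                                         "pause_percent")) {
  stopifnot(is.data.frame(metrics), "group" %in% names(metrics))
  if (any(!variables %in% names(metrics))) {
    stop("metrics table lacks column(s): ",
         paste(setdiff(variables, names(metrics)), collapse = ", "),
         call. = FALSE)
  }
  groups <- unique(metrics$group)
  for (g in groups) {
    if (!sum(metrics$group == g)) stop("empty group: ", g, call. = FALSE)
  }
  rows <- list()
  for (v in variables) {
    for (g in groups) {
      x <- metrics[[v]][metrics$group == g]
      n <- length(x)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, group = g, n = n, mean = mean(x),
        sem = if (n > 1) stats::sd(x) / sqrt(n) else 0,
        n_flag = as.integer(n == 1), stringsAsFactors = FALSE)
    }
  }
  list(per_track = metrics, summary = do.call(rbind, rows))
}
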