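#' Simulate a single cargo trajectory
#'
#' Generates one ground-truth trajectory of the run-pause-switch motility
#' model on the acquisition time grid. Position is measured in um from the
#' distal (axon-chamber) end toward the soma, so retrograde motion increases
#' position. Each inter-frame step is labelled with the ground-truth state
#' (`"retro-run"`, `"antero-run"` or `"pause"`), giving one fewer label than
#' time points.
#'
#' At every step the cargo first updates its state (run -> pause with
#' per-step probability `p_pause * frame_interval`; pause -> run with
#' per-step probability `frame_interval / mean_pause`, resuming anterograde
#' with probability `p_switch`), then moves: run displacement is
#' `direction * v * frame_interval * max(0, 1 + speed_cv * z)` with
#' `z ~ N(0,1)`; pauses do not move. A cargo hitting either axon end
#' reflects and resumes moving inward.
#'
#' @param params A [transport_params()] object.
#' @param acq An [acquisition_config()] object.
#' @param seed Integer seed; trajectories are bit-identical for equal seeds.
#' @param start_position Optional start position in um; by default drawn
#'   uniformly from 10-50% of the axon length (seeded).
#' @return An object of class `trajectory` with fields `times` (s),
#'   `positions` (um) and `state_labels`.
#' @export
simulate_trajectory <- function(params, acq, seed,
                                start_position = NULL) {
  stopifnot(inherits(params, "transport_params"),
            inherits(acq, "acquisition_config"))
  run_seeded(seed, {
    n <- acq$n_frames
    dt <- acq$frame_interval
    L <- params$axon_length
    q_pause <- min(1, params$p_pause * dt)
    r_exit <- min(1, dt / params$mean_pause)
    if (is.null(start_position)) {
      start_position <- stats::runif(1, 0.1, 0.5) * L
    }
    check_number(start_position, "start_position", lower = 0, upper = L)
    u_trans <- stats::runif(n - 1)
    u_switch <- stats::runif(n - 1)
    z <- stats::rnorm(n - 1)

    pos <- numeric(n)
    lab <- character(n - 1)
    pos[1] <- start_position
    paused <- FALSE
    dir <- 1L # +1 retrograde (toward soma), -1 anterograde
    for (i in seq_len(n - 1)) {
      if (paused) {
        if (u_trans[i] < r_exit) {
          paused <- FALSE
          dir <- if (u_switch[i] < params$p_switch) -1L else 1L
        }
      } else if (u_trans[i] < q_pause) {
        paused <- TRUE
      }
      if (paused) {
        lab[i] <- "pause"
        pos[i + 1] <- pos[i]
      } else {
        v <- if (dir > 0) params$v_retro else params$v_antero
        lab[i] <- if (dir > 0) "retro-run" else "antero-run"
        p2 <- pos[i] + dir * v * dt * max(0, 1 + params$speed_cv * z[i])
        if (p2 > L) {
          p2 <- 2 * L - p2
          dir <- -dir
        }
        if (p2 < 0) {
          p2 <- -p2
          dir <- -dir
        }
        pos[i + 1] <- min(max(p2, 0), L)
      }
    }
    structure(list(times = (seq_len(n) - 1) * dt, positions = pos,
                   state_labels = lab, params = params, acq = acq,
                   seed = seed),
              class = "trajectory")
  })
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "Trajectory: %d frames over %.4g s; position %.1f -> %.1f um; pause %.1f%%\n",
    length(x$positions), max(x$times), x$positions[1],
    x$positions[length(x$positions)], 100 * truth_pause_fraction(x)))
  invisible(x)
}

#' Specification of a simulated cohort
#'
#' @param groups Named list of [transport_params()], one per group; names
#'   must be unique and non-empty.
#' @param n_tracks Number of tracks per group: a single count applied to all
#'   groups, or a vector named by group.
#' @param seed Integer cohort seed. Per-track seeds are derived
#'   deterministically from (seed, group name, track index), independent of
#'   generation order.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups, n_tracks, seed = 1) {
  stopifnot(is.list(groups), length(groups) >= 1)
  if (is.null(names(groups)) || anyDuplicated(names(groups)) ||
      any(!nzchar(names(groups)))) {
    stop("'groups' must be a uniquely named list of transport_params",
         call. = FALSE)
  }
  for (g in names(groups)) {
    if (!inherits(groups[[g]], "transport_params")) {
      stop("group '", g, "' is not a transport_params object", call. = FALSE)
    }
  }
  if (length(n_tracks) == 1L && is.null(names(n_tracks))) {
    n_tracks <- stats::setNames(rep(n_tracks, length(groups)), names(groups))
  }
  if (!setequal(names(n_tracks), names(groups))) {
    stop("'n_tracks' must be a single count or named per group",
         call. = FALSE)
  }
  n_tracks <- n_tracks[names(groups)]
  if (any(n_tracks < 1)) stop("each group needs n_tracks >= 1", call. = FALSE)
  structure(list(groups = groups, n_tracks = n_tracks,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a cohort of trajectories
#'
#' @param spec A [cohort_spec()].
#' @param acq An [acquisition_config()].
#' @return An object of class `transport_cohort`: a list of `trajectory`
#'   objects (each carrying `group` and `track_id`) plus the spec.
#' @export
simulate_cohort <- function(spec, acq) {
  stopifnot(inherits(spec, "cohort_spec"),
            inherits(acq, "acquisition_config"))
  out <- list()
  for (g in names(spec$groups)) {
    for (k in seq_len(spec$n_tracks[[g]])) {
      tr <- simulate_trajectory(spec$groups[[g]], acq,
                                seed = derive_seed(spec$seed, g, k))
      tr$group <- g
      tr$track_id <- sprintf("%s_%03d", g, k)
      out[[length(out) + 1L]] <- tr
    }
  }
  structure(list(trajectories = out, spec = spec, acq = acq),
            class = "transport_cohort")
}

#' @export
print.transport_cohort <- function(x, ...) {
  tab <- table(vapply(x$trajectories, `[[`, character(1), "group"))
  cat("Simulated cohort:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Closed-form expectations of the transport metrics
#'
#' Renewal-theory expectations for the run-pause model without direction
#' switches: runs are geometric with mean `1/p_pause` s, pauses geometric
#' with mean `mean_pause` s, so the long-run pause-time fraction is
#' `f = p_pause * mean_pause / (1 + p_pause * mean_pause)`. The expected
#' moving velocity is `v_retro` and the expected average velocity
#' `v_retro * (1 - f)`. Only valid (and only provided) for `p_switch = 0`;
#' with switches there is no closed form and Monte-Carlo simulation via
#' [simulate_cohort()] should be used.
#'
#' @param params A [transport_params()] with `p_switch = 0`.
#' @param acq An [acquisition_config()] (kept for interface symmetry; the
#'   expectations are per-second quantities).
#' @return List with `pause_fraction`, `pause_percent`, `moving_velocity`
#'   and `average_velocity`.
#' @export
expected_metrics <- function(params, acq = acquisition_config()) {
  stopifnot(inherits(params, "transport_params"))
  if (params$p_switch > 0) {
    stop("no closed form when p_switch > 0; use Monte Carlo ",
         "(simulate_cohort)", call. = FALSE)
  }
  f <- params$p_pause * params$mean_pause /
    (1 + params$p_pause * params$mean_pause)
  list(pause_fraction = f, pause_percent = 100 * f,
       moving_velocity = params$v_retro,
       average_velocity = params$v_retro * (1 - f))
}

# Ground-truth summaries -------------------------------------------------

#' Ground-truth pause fraction of a simulated trajectory
#'
#' Fraction of inter-frame steps whose true state is `"pause"`.
#' @param traj A `trajectory`.
#' @return Number in `[0, 1]`.
#' @export
truth_pause_fraction <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  mean(traj$state_labels == "pause")
}

#' Ground-truth mean run speed of a simulated trajectory
#'
#' Mean per-step speed (|displacement| / frame interval) over steps whose
#' true state is a run.
#' @param traj A `trajectory`.
#' @return Speed in um/s (NA if the trajectory never runs).
#' @export
truth_run_speed <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  moving <- traj$state_labels != "pause"
  if (!any(moving)) return(NA_real_)
  d <- abs(diff(traj$positions))[moving]
  mean(d) / traj$acq$frame_interval
}

# Trajectory export / import --------------------------------------------

cohort_to_frame <- function(cohort) {
  do.call(rbind, lapply(cohort$trajectories, function(tr) {
    n <- length(tr$positions)
    data.frame(track_id = tr$track_id %||% "track_1",
               group = tr$group %||% "group_1",
               frame = seq_len(n),
               time_s = tr$times,
               position_um = tr$positions,
               true_state = c(tr$state_labels, tr$state_labels[n - 1]),
               stringsAsFactors = FALSE)
  }))
}

#' Export simulated trajectories to CSV
#'
#' One row per track and frame with columns `track_id`, `group`, `frame`,
#' `time_s`, `position_um`, `true_state` (the state of the step leaving the
#' frame; the last frame repeats the final step's state). Provenance
#' (package version, cohort seed) is written as `#` header lines.
#'
#' @param cohort A `transport_cohort`.
#' @param file Output CSV path.
#' @return The file path, invisibly.
#' @export
write_trajectories <- function(cohort, file) {
  stopifnot(inherits(cohort, "transport_cohort"))
  write_csv_prov(cohort_to_frame(cohort), file,
                 provenance = list(seed = cohort$spec$seed,
                                   frame_interval_s = cohort$acq$frame_interval,
                                   n_tracks = sum(cohort$spec$n_tracks)))
  invisible(file)
}

#' Read a trajectory/track table written by [write_trajectories()]
#'
#' @param file CSV path.
#' @return A data frame with one row per track and frame.
#' @export
read_trajectories <- function(file) {
  df <- read_csv_prov(file)
  need <- c("track_id", "group", "frame", "time_s", "position_um")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("track table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df
}
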