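#' Cargo motility parameters for the run-pause-switch transport model
#'
#' Parameters of the stochastic motility model used to emulate retrogradely
#' biased axonal transport of signalling endosomes (e.g. quantum-dot-labelled
#' BDNF). A cargo alternates between processive runs and pauses; at every
#' pause exit it resumes anterogradely with probability `p_switch` (a brief
#' excursion) and retrogradely otherwise, which keeps the long-run motion
#' retrograde-dominant.
#'
#' @param v_retro Retrograde run speed, um/s (>= 0).
#' @param v_antero Anterograde run speed, um/s (>= 0).
#' @param p_pause Per-second probability of entering a pause from a run.
#' @param mean_pause Mean pause duration in seconds (> 0). Pause dwell is
#'   geometric at frame resolution (memoryless), so the per-frame exit
#'   probability is `frame_interval / mean_pause`.
#' @param p_switch Probability, applied at each pause exit, that the run
#'   resumes in the anterograde direction.
#' @param speed_cv Multiplicative per-step speed noise coefficient (>= 0);
#'   each run step is scaled by `max(0, 1 + speed_cv * N(0,1))`.
#' @param axon_length Axon (microgroove) length in um; default 450.
#'
#' @return An object of class `transport_params`.
#' @seealso [simulate_trajectory()], [expected_metrics()], [asyn_like_params()]
#' @export
transport_params <- function(v_retro = 1.0, v_antero = 0.8, p_pause = 0.1,
                             mean_pause = 3, p_switch = 0.05, speed_cv = 0.1,
                             axon_length = 450) {
  check_number(v_retro, "v_retro", lower = 0)
  check_number(v_antero, "v_antero", lower = 0)
  check_probability(p_pause, "p_pause")
  check_number(mean_pause, "mean_pause", lower = 0, strict_lower = TRUE)
  check_probability(p_switch, "p_switch")
  check_number(speed_cv, "speed_cv", lower = 0)
  check_number(axon_length, "axon_length", lower = 0, strict_lower = TRUE)
  structure(list(v_retro = v_retro, v_antero = v_antero, p_pause = p_pause,
                 mean_pause = mean_pause, p_switch = p_switch,
                 speed_cv = speed_cv, axon_length = axon_length),
            class = "transport_params")
}

#' Demonstration motility profile with alpha-synuclein-like transport deficits
#'
#' Returns the package's built-in "treated" profile: run speeds scaled to
#' 0.635 of the control profile (a 36.5% moving-velocity reduction), pause
#' entry raised from 0.1/s to 0.25/s with mean pause lengthened from 3 s to
#' 4 s (expected pause fraction 23.1% -> 50%), and more frequent direction
#' switches. Used by the end-to-end demo and recovery tests.
#'
#' @param control A `transport_params` object to derive the profile from.
#' @param speed_factor Multiplier applied to both run speeds.
#' @return A `transport_params` object.
#' @export
asyn_like_params <- function(control = transport_params(),
                             speed_factor = 0.635) {
  stopifnot(inherits(control, "transport_params"))
  transport_params(v_retro = control$v_retro * speed_factor,
                   v_antero = control$v_antero * speed_factor,
                   p_pause = 0.25, mean_pause = 4, p_switch = 0.15,
                   speed_cv = control$speed_cv,
                   axon_length = control$axon_length)
}

#' @export
print.transport_params <- function(x, ...) {
  cat("Transport parameters (run-pause-switch model)\n")
  cat(sprintf("  run speeds: retro %.3f, antero %.3f um/s\n",
              x$v_retro, x$v_antero))
  cat(sprintf("  pause entry %.3f /s, mean pause %.2f s, switch %.3f\n",
              x$p_pause, x$mean_pause, x$p_switch))
  cat(sprintf("  speed cv %.3f, axon length %.0f um\n",
              x$speed_cv, x$axon_length))
  invisible(x)
}

#' Acquisition settings of a time-lapse movie
#'
#' @param frame_interval Seconds between frames (default 1 s).
#' @param duration Total movie duration in seconds (default 120 s); must be a
#'   positive multiple of `frame_interval`. The number of frames is
#'   `duration / frame_interval`; frame `i` is acquired at
#'   `t = (i - 1) * frame_interval`.
#' @param pixel_size Image calibration in um per pixel (default 0.16).
#' @return An object of class `acquisition_config` with an `n_frames` field.
#' @export
acquisition_config <- function(frame_interval = 1.0, duration = 120,
                               pixel_size = 0.16) {
  check_number(frame_interval, "frame_interval", lower = 0,
               strict_lower = TRUE)
  check_number(duration, "duration", lower = 0, strict_lower = TRUE)
  check_number(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  n <- duration / frame_interval
  if (abs(n - round(n)) > 1e-9 || round(n) < 2) {
    stop("'duration' must be a positive multiple (>= 2) of 'frame_interval'",
         call. = FALSE)
  }
  structure(list(frame_interval = frame_interval, duration = duration,
                 pixel_size = pixel_size, n_frames = as.integer(round(n))),
            class = "acquisition_config")
}

#' @export
print.acquisition_config <- function(x, ...) {
  cat(sprintf(
    "Acquisition: %d frames, %.3g s/frame (%.4g s total), %.3g um/px\n",
    x$n_frames, x$frame_interval, x$duration, x$pixel_size))
  invisible(x)
}
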