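test_that("segment angles follow the kymograph geometry", {
  # equal display steps, retrograde: -45 degrees
  expect_equal(segment_angle(u = 2 * 0.16, duration = 2,
                             row_scale = 1, col_scale = 0.16), -45)
  expect_equal(segment_angle(u = 0, duration = 5), -90)
  expect_equal(segment_angle(u = -3 * 0.16, duration = 3,
                             row_scale = 1, col_scale = 0.16), -135)
  expect_error(segment_angle(u = 1, duration = 0), "positive")
})

test_that("angle classification matches the published cut-offs and closure rules", {
  expect_equal(classify_angle(-45), "retrograde")
  expect_equal(classify_angle(-90), "stationary")
  expect_equal(classify_angle(-120), "anterograde")
  # boundaries resolve per the documented rules
  expect_equal(classify_angle(-1), "retrograde")
  expect_equal(classify_angle(-89.4), "retrograde")
  expect_equal(classify_angle(-90.6), "anterograde")
  expect_equal(classify_angle(-89.5), "stationary")
  expect_equal(classify_angle(-90.5), "stationary")
  # the two 0.1-degree printed gaps close into stationary
  expect_equal(classify_angle(-89.45), "stationary")
  expect_equal(classify_angle(-90.55), "stationary")
  # near-instantaneous jumps are flagged, not silently classified
  expect_warning(cls <- classify_angle(-0.5), "unclassified")
  expect_equal(cls, "unclassified")
  expect_error(classify_angle(-180), "domain")
  expect_error(classify_angle(5), "domain")
})

test_that("every angle in (-180, -1] receives exactly one direction class", {
  theta <- seq(-179.999, -1, by = 0.007)
  cls <- classify_angle(theta)
  expect_true(all(cls %in% c("retrograde", "anterograde", "stationary")))
  expect_equal(sum(cls == "retrograde"), sum(theta >= -89.4 & theta <= -1))
  expect_equal(sum(cls == "anterograde"), sum(theta <= -90.6))
})

test_that("track metrics implement the velocity and pause definitions", {
  segs <- structure(
    data.frame(class = c("retrograde", "stationary"),
               start_frame = c(1, 16), end_frame = c(16, 21),
               start_pos = c(0, 10), end_pos = c(10, 10),
               duration = c(15, 5), u = c(10, 0)),
    class = c("track_segments", "data.frame"),
    track_id = "hand_built", total_time = 20, row_scale = 1,
    col_scale = 0.16, delta = 0.1)
  m <- track_metrics(segs)
  expect_equal(m$average_velocity, 0.5)
  expect_equal(m$moving_velocity, 10 / 15)
  expect_equal(m$pause_percent, 25)
  expect_equal(m$n_pause_events, 1)

  # no pauses: the two velocities coincide
  run <- segment_track(cargo_track(1:11, seq(0, 10, by = 1)))
  m2 <- track_metrics(run)
  expect_equal(m2$average_velocity, m2$moving_velocity)

  # fully stationary track
  still <- segment_track(cargo_track(1:121, rep(4, 121)))
  m3 <- track_metrics(still)
  expect_equal(m3$pause_percent, 100)
  expect_equal(m3$average_velocity, 0)
  expect_equal(m3$moving_velocity, 0)

  expect_error(track_metrics(run, total_time = 0), "positive")
})

test_that("path distance counts direction switches that net distance cancels", {
  zig <- segment_track(cargo_track(1:7, c(0, 1, 2, 3, 2, 1, 0)))
  expect_equal(track_metrics(zig, distance_mode = "path")$distance, 6)
  expect_equal(track_metrics(zig, distance_mode = "net")$distance, 0)
})

test_that("angle classes agree with displacement classes for resolved segments", {
  acq <- acquisition_config()
  coh <- simulate_cohort(cohort_spec(list(g = transport_params(p_switch = 0.3)),
                                     n_tracks = 10, seed = 5), acq)
  for (tr in coh$trajectories) {
    segs <- annotate_angles(segment_track(trajectory_to_track(tr)))
    moving <- segs$class != "stationary" &
      abs(segs$u) / (segs$duration / attr(segs, "row_scale")) >=
        attr(segs, "delta")
    expect_equal(segs$angle_class[moving], segs$class[moving])
  }
})

test_that("average velocity never exceeds moving velocity; equality iff no pause", {
  acq <- acquisition_config()
  coh <- simulate_cohort(cohort_spec(list(a = transport_params(),
                                          b = asyn_like_params()),
                                     n_tracks = 10, seed = 8), acq)
  met <- analyze_tracks(lapply(coh$trajectories, trajectory_to_track))
  expect_true(all(met$average_velocity <= met$moving_velocity + 1e-12))
  eq <- abs(met$average_velocity - met$moving_velocity) < 1e-12
  expect_equal(eq, met$pause_time == 0)
})

test_that("cohort summaries handle singletons and identical groups", {
  one <- analyze_tracks(list(cargo_track(1:11, seq(0, 10), group = "g1")))
  cm <- cohort_metrics(one)
  expect_equal(cm$summary$mean[cm$summary$variable == "moving_velocity"], 1)
  expect_true(all(cm$summary$sem == 0))
  expect_true(all(cm$summary$n_flag == 1))

  t1 <- cargo_track(1:11, seq(0, 10), group = "g1", track_id = "a")
  t2 <- cargo_track(1:11, seq(0, 10), group = "g2", track_id = "b")
  cm2 <- cohort_metrics(analyze_tracks(list(t1, t2)))
  s <- cm2$summary
  for (v in unique(s$variable)) {
    expect_equal(s$mean[s$variable == v][1], s$mean[s$variable == v][2])
  }
})

test_that("pipeline group means track the closed form without switches", {
  p <- free_params(v = 1, p_pause = 0.1, mean_pause = 3, speed_cv = 0.05)
  acq <- acquisition_config(duration = 300)
  coh <- simulate_cohort(cohort_spec(list(ctl = p), n_tracks = 100,
                                     seed = 13), acq)
  met <- analyze_tracks(lapply(coh$trajectories, trajectory_to_track))
  em <- expected_metrics(p)
  expect_lt(abs(mean(met$moving_velocity) - em$moving_velocity) /
              em$moving_velocity, 0.05)
  expect_lt(abs(mean(met$average_velocity) - em$average_velocity) /
              em$average_velocity, 0.05)
  expect_lt(abs(mean(met$pause_percent) - em$pause_percent) /
              em$pause_percent, 0.05)
})
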