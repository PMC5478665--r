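acq120 <- acquisition_config()

test_that("noiseless pause-free limit advances exactly v per frame, all retro", {
  p <- transport_params(v_retro = 1.0, p_pause = 0, p_switch = 0,
                        speed_cv = 0)
  tr <- simulate_trajectory(p, acq120, seed = 3, start_position = 100)
  expect_length(tr$positions, 120)
  expect_length(tr$state_labels, 119)
  expect_equal(diff(tr$positions), rep(1.0, 119))
  expect_true(all(tr$state_labels == "retro-run"))
  expect_equal(tr$times, 0:119)
})

test_that("immobile limit keeps positions constant", {
  p <- transport_params(v_retro = 0, v_antero = 0, speed_cv = 0)
  tr <- simulate_trajectory(p, acq120, seed = 5)
  expect_equal(diff(tr$positions), rep(0, 119))
  m <- track_metrics(segment_track(trajectory_to_track(tr)))
  expect_equal(m$pause_percent, 100)
})

test_that("trajectories are deterministic given the seed and bounded", {
  p <- transport_params()
  a <- simulate_trajectory(p, acq120, seed = 17)
  b <- simulate_trajectory(p, acq120, seed = 17)
  expect_identical(a$positions, b$positions)
  expect_identical(a$state_labels, b$state_labels)
  for (s in c(1, 2, 99)) {
    tr <- simulate_trajectory(transport_params(p_switch = 0.5,
                                               axon_length = 30),
                              acq120, seed = s)
    expect_true(all(tr$positions >= 0 & tr$positions <= 30))
  }
})

test_that("parameter validation rejects invalid probabilities and speeds", {
  expect_error(transport_params(p_pause = 1.2), "p_pause")
  expect_error(transport_params(v_retro = -1), "v_retro")
  expect_error(transport_params(mean_pause = 0), "mean_pause")
  expect_error(acquisition_config(duration = 7, frame_interval = 2),
               "multiple")
})

test_that("Monte-Carlo pause fraction matches the renewal closed form", {
  p <- free_params(p_pause = 0.2, mean_pause = 3)
  acq <- acquisition_config(duration = 10000)
  tr <- simulate_trajectory(p, acq, seed = 1, start_position = 5e4)
  em <- expected_metrics(p)
  expect_equal(em$pause_fraction, 0.2 * 3 / (1 + 0.2 * 3))
  expect_lt(abs(truth_pause_fraction(tr) - em$pause_fraction), 0.02)
  avg <- sum(abs(diff(tr$positions))) / (length(tr$positions) - 1)
  expect_lt(abs(avg - em$average_velocity) / em$average_velocity, 0.03)
})

test_that("expected_metrics covers limits and refuses open cases", {
  p0 <- transport_params(p_pause = 0, p_switch = 0)
  em <- expected_metrics(p0)
  expect_equal(em$pause_percent, 0)
  expect_equal(em$average_velocity, em$moving_velocity)
  expect_error(expected_metrics(transport_params(p_switch = 0.1)),
               "Monte Carlo")
})

test_that("cohorts are reproducible and keep group bookkeeping", {
  spec <- cohort_spec(list(g1 = transport_params()), n_tracks = 3, seed = 7)
  a <- simulate_cohort(spec, acq120)
  b <- simulate_cohort(spec, acq120)
  expect_identical(lapply(a$trajectories, `[[`, "positions"),
                   lapply(b$trajectories, `[[`, "positions"))
  spec2 <- cohort_spec(list(ctl = transport_params(),
                            tg = asyn_like_params()),
                       n_tracks = 20, seed = 2)
  coh <- simulate_cohort(spec2, acq120)
  expect_length(coh$trajectories, 40)
  expect_equal(table(vapply(coh$trajectories, `[[`, character(1), "group")),
               table(rep(c("ctl", "tg"), each = 20)))
})

test_that("injected run-speed ratio is recovered from ground-truth states", {
  ctl <- transport_params(v_retro = 1.0, v_antero = 1.0)
  tg <- transport_params(v_retro = 0.635, v_antero = 0.635)
  spec <- cohort_spec(list(control = ctl, asyn = tg), n_tracks = 50,
                      seed = 11)
  coh <- simulate_cohort(spec, acq120)
  speed <- vapply(coh$trajectories, truth_run_speed, numeric(1))
  grp <- vapply(coh$trajectories, `[[`, character(1), "group")
  ratio <- mean(speed[grp == "asyn"], na.rm = TRUE) /
    mean(speed[grp == "control"], na.rm = TRUE)
  expect_lt(abs(ratio - 0.635), 0.02)
})

test_that("trajectory tables round-trip through CSV", {
  spec <- cohort_spec(list(ctl = transport_params()), n_tracks = 2, seed = 4)
  coh <- simulate_cohort(spec, acq120)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectories(coh, f)
  df <- read_trajectories(f)
  expect_equal(nrow(df), 2 * 120)
  expect_equal(df$position_um[df$track_id == "ctl_001"],
               coh$trajectories[[1]]$positions)
  expect_error(read_trajectories(withr::local_tempfile(lines = "a,b\n1,2",
                                                       fileext = ".csv")),
               "lacks column")
})
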