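test_that("an all-zero kymograph yields zero detections", {
  k <- make_kymo(matrix(0, 10, 50))
  d <- detect_per_frame(k)
  expect_equal(nrow(d), 0)
})

test_that("a single noiseless ridge gives one sub-pixel detection per row", {
  centres <- 10 + 0.8 * (0:19) # deliberately non-integer drift
  k <- make_kymo(ridge_matrix(cbind(centres), n_cols = 60))
  d <- detect_per_frame(k, min_snr = 3)
  expect_equal(d$frame, 1:20)
  expect_true(all(abs(d$position - centres) < 0.1))
})

test_that("two well-separated ridges stay two tracks with no identity swaps", {
  c1 <- 10 + 0.5 * (0:19)
  c2 <- 45 - 0.5 * (0:19)
  k <- make_kymo(ridge_matrix(cbind(c1, c2), n_cols = 60), col_scale = 0.16)
  d <- detect_per_frame(k, min_snr = 3)
  expect_equal(as.vector(table(d$frame)), rep(2L, 20))
  tks <- link_tracks(d, k, max_jump = 0.5, max_gap = 2, min_track_len = 10)
  expect_length(tks, 2)
  pos1 <- tks[[1]]$position_col
  pos2 <- tks[[2]]$position_col
  if (pos1[1] > pos2[1]) {
    tmp <- pos1
    pos1 <- pos2
    pos2 <- tmp
  }
  expect_true(all(abs(pos1 - c1) < 0.2))
  expect_true(all(abs(pos2 - c2) < 0.2))
})

test_that("detection dropouts within max_gap are bridged into one track", {
  centres <- 10 + 0.5 * (0:19)
  m <- ridge_matrix(cbind(centres), n_cols = 60)
  m[8:9, ] <- 0 # 2-frame blink
  k <- make_kymo(m, col_scale = 0.16)
  d <- detect_per_frame(k, min_snr = 3)
  tks <- link_tracks(d, k, max_jump = 0.5, max_gap = 3, min_track_len = 10)
  expect_length(tks, 1)
  expect_equal(tks[[1]]$frame, 1:20)
  expect_equal(which(tks[[1]]$interpolated), 8:9)
  # interpolated frames continue the run: no spurious pause
  segs <- segment_track(tks[[1]], delta = 0.03)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$class, "retrograde")
})

test_that("tracks shorter than min_track_len are discarded", {
  centres <- rep(20, 5)
  k <- make_kymo(ridge_matrix(cbind(centres), n_cols = 60))
  d <- detect_per_frame(k)
  expect_length(link_tracks(d, k, max_jump = 1, min_track_len = 10), 0)
})

test_that("segment_track follows the displacement definitions exactly", {
  # flat track: one stationary segment covering everything
  flat <- cargo_track(1:6, rep(3, 6), track_id = "flat")
  s <- segment_track(flat, delta = 0.5)
  expect_equal(nrow(s), 1)
  expect_equal(s$class, "stationary")
  expect_equal(s$duration, 5)

  # 0,1,2,2,2,3 with delta 0.5: retro 2 s, stationary 2 s, retro 1 s
  tr <- cargo_track(1:6, c(0, 1, 2, 2, 2, 3))
  s <- segment_track(tr, delta = 0.5)
  expect_equal(s$class, c("retrograde", "stationary", "retrograde"))
  expect_equal(s$duration, c(2, 2, 1))
  expect_equal(s$u, c(2, 0, 1))

  expect_error(segment_track(tr, delta = 0), "positive")
})

test_that("segments tile the track exactly for arbitrary position series", {
  for (s in 1:5) {
    set.seed(s)
    n <- 40
    pos <- cumsum(c(10, rnorm(n - 1, mean = 0.3, sd = 0.6)))
    tr <- cargo_track(1:n, pos)
    seg <- segment_track(tr, delta = 0.2)
    expect_equal(sum(seg$duration), n - 1)
    expect_equal(seg$start_frame[-1], seg$end_frame[-nrow(seg)])
    expect_equal(seg$start_pos[1], pos[1])
    expect_equal(seg$end_pos[nrow(seg)], pos[n])
  }
})

test_that("noiseless imaging chain recovers ground-truth positions and states", {
  acq <- acquisition_config() # 120 s at 1 frame/s
  groups <- list(control = transport_params(),
                 asyn = asyn_like_params())
  coh <- simulate_cohort(cohort_spec(groups, n_tracks = 3, seed = 21), acq)
  path <- straight_axon_path(450, acq$pixel_size, y = 12.5)
  opt <- optics_config(noise = "none", image_height = 24)
  lab_map <- truth_class_map
  for (tr in coh$trajectories) {
    stk <- render_stack(tr, path, acq, opt)
    k <- build_kymograph(stk, path)
    tks <- link_tracks(detect_per_frame(k), k, max_jump = 2, max_gap = 3,
                       min_track_len = 10)
    expect_length(tks, 1)
    tk <- tks[[1]]
    expect_equal(tk$frame, 1:120)
    truth_col <- tr$positions / acq$pixel_size + 1
    rmse <- sqrt(mean((tk$position_col - truth_col)^2))
    expect_lt(rmse, 0.5)
    segs <- segment_track(tk, delta = 0.1)
    agree <- mean(segment_step_labels(segs) ==
                    unname(lab_map[tr$state_labels]))
    expect_gte(agree, 0.95)
    truth_pause <- 100 * truth_pause_fraction(tr)
    expect_lt(abs(track_metrics(segs)$pause_percent - truth_pause), 5)
  }
})
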