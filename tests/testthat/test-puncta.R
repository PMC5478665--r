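test_that("area binning follows the closed median interval and sums to 100", {
  fr <- bin_areas(c(0.3, 0.5, 1.0))
  expect_equal(fr$percent, rep(100 / 3, 3))
  expect_equal(sum(fr$percent), 100)
  # boundary values belong to the median class
  fr2 <- bin_areas(c(0.45, 0.9))
  expect_equal(fr2$count, c(0, 2, 0))
  expect_error(bin_areas(numeric(0)), "no areas")
})

test_that("binned frequencies match analytic lognormal mixture masses", {
  set.seed(42)
  n <- 1000
  pick <- runif(n) < 0.6
  areas <- ifelse(pick, rlnorm(n, log(0.35), 0.4), rlnorm(n, log(1.1), 0.3))
  mass <- function(lo, hi) {
    0.6 * (plnorm(hi, log(0.35), 0.4) - plnorm(lo, log(0.35), 0.4)) +
      0.4 * (plnorm(hi, log(1.1), 0.3) - plnorm(lo, log(1.1), 0.3))
  }
  truth <- 100 * c(mass(0, 0.45), mass(0.45, 0.9), mass(0.9, Inf))
  fr <- bin_areas(areas)
  expect_true(all(abs(fr$percent - truth) < 3))
  expect_equal(sum(fr$percent), 100)
})

test_that("a filled disk is segmented with the correct calibrated area", {
  fx <- generate_puncta_image(1, radius_px = 5, image_size = c(64, 64),
                              pixel_size = 0.1, noise_sd = 0, seed = 2)
  rec <- segment_objects(fx$image, pixel_size = 0.1)
  expect_equal(nrow(rec), 1)
  expect_lt(abs(rec$area_um2 - pi * 0.5^2) / (pi * 0.5^2), 0.10)
})

test_that("blank and constant images yield no objects", {
  expect_warning(rec <- segment_objects(matrix(0.2, 32, 32),
                                        pixel_size = 0.1), "constant")
  expect_equal(nrow(rec), 0)
  fx <- generate_puncta_image(0, image_size = c(32, 32), noise_sd = 0,
                              background = 0.1, seed = 1)
  expect_equal(nrow(fx$truth), 0)
})

test_that("two disjoint disks give two records with correct centroids", {
  fx <- generate_puncta_image(2, radius_px = 6, image_size = c(96, 96),
                              pixel_size = 0.1, noise_sd = 0, seed = 3)
  rec <- segment_objects(fx$image, pixel_size = 0.1)
  expect_equal(nrow(rec), 2)
  for (i in 1:2) {
    d <- sqrt((rec$centroid_x - fx$truth$x[i])^2 +
                (rec$centroid_y - fx$truth$y[i])^2)
    expect_lt(min(d), 1)
  }
})

test_that("labelling is 8-connected and min_area_px filters speckle", {
  img <- matrix(0, 12, 12)
  img[3, 3] <- img[4, 4] <- img[5, 5] <- img[6, 6] <- 1 # diagonal chain
  rec <- segment_objects(img, pixel_size = 1, min_area_px = 4,
                         threshold = 0.5)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$area_px, 4)
  # a single stray pixel is removed by the default min_area_px
  img2 <- matrix(0, 12, 12)
  img2[2, 2] <- 1
  img2[6:9, 6:9] <- 1
  rec2 <- segment_objects(img2, pixel_size = 1, threshold = 0.5)
  expect_equal(nrow(rec2), 1)
  expect_equal(rec2$area_px, 16)
})

test_that("area calibration scales with the square of the pixel size", {
  fx <- generate_puncta_image(3, radius_px = 5, image_size = c(96, 96),
                              pixel_size = 0.1, noise_sd = 0, seed = 4)
  a1 <- segment_objects(fx$image, pixel_size = 0.1)$area_um2
  a2 <- segment_objects(fx$image, pixel_size = 0.2)$area_um2
  expect_equal(a2, 4 * a1)
})

test_that("generation is deterministic and bounded retries fail loudly", {
  a <- generate_puncta_image(10, radius_px = 4:8, seed = 7)
  b <- generate_puncta_image(10, radius_px = 4:8, seed = 7)
  expect_identical(a$image, b$image)
  expect_error(generate_puncta_image(500, radius_px = 10,
                                     image_size = c(64, 64), seed = 1,
                                     max_tries = 50),
               "non-overlapping")
})

test_that("fifty known disks are recovered in count and per-object area", {
  fx <- generate_puncta_image(50, radius_px = function(n) runif(n, 4, 8),
                              image_size = c(512, 512), pixel_size = 0.1,
                              noise_sd = 0.02, seed = 11)
  rec <- segment_objects(fx$image, pixel_size = fx$pixel_size)
  expect_lte(abs(nrow(rec) - 50), 1)
  # match each truth object to the nearest segmented centroid
  rel_err <- vapply(seq_len(nrow(fx$truth)), function(i) {
    d <- sqrt((rec$centroid_x - fx$truth$x[i])^2 +
                (rec$centroid_y - fx$truth$y[i])^2)
    j <- which.min(d)
    abs(rec$area_um2[j] - fx$truth$area_um2[i]) / fx$truth$area_um2[i]
  }, numeric(1))
  expect_lt(max(rel_err), 0.15)
})
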