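# Segmentation, ratio computation, linking, kinematics, target geometry.

test_that("blank frames yield a no-cell signal", {
  set.seed(1)
  a <- matrix(100 + rnorm(320 * 64, 0, 50), 320, 64)
  b <- matrix(100 + rnorm(320 * 64, 0, 50), 320, 64)
  expect_false(segment_frame(a, b)$found)
  flat <- matrix(0, 320, 64)
  expect_false(segment_frame(flat, flat)$found)
})

test_that("noise-free synthetic cells segment with Jaccard exactly 1", {
  sc <- simulate_scene("no_response", seed = 2, n_frames = 2)
  seg <- segment_frame(sc$frames$ch1[[1]] - 100, sc$frames$ch2[[1]] - 100)
  expect_true(seg$found)
  expect_equal(jaccard_index(seg$mask, sc$track$masks[[1]]), 1)
  # non-mask pixels are undefined in the returned channels
  expect_true(all(is.na(seg$donor_bg[!seg$mask])))
})

test_that("segmentation is invariant to a common intensity rescaling", {
  acq <- acquisition_params(noise = list(gaussian_sd = 40, poisson = FALSE))
  sc <- simulate_scene("no_response", acq = acq, seed = 5, n_frames = 2)
  d <- sc$frames$ch1[[1]] - 100; a <- sc$frames$ch2[[1]] - 100
  m1 <- segment_frame(d, a)$mask
  m2 <- segment_frame(d * 13.7, a * 13.7)$mask
  expect_identical(m1, m2)
})

test_that("ratio image follows the configured orientation and masks NAs", {
  m <- rect_mask(20, 20, 5, 14, 5, 14)
  d <- matrix(50, 20, 20); a <- matrix(100, 20, 20)
  r <- compute_ratio_image(d, a, m)
  expect_equal(unique(r[m]), 2)
  expect_true(all(is.na(r[!m])))
  r1 <- compute_ratio_image(d, d, m)
  expect_equal(unique(r1[m]), 1)
  # donor <= 0 pixels become undefined, exactly
  d2 <- d; d2[6:8, 6] <- 0
  r2 <- compute_ratio_image(d2, a, m)
  expect_identical(sum(is.na(r2[m])), 3L)
  expect_error(compute_ratio_image(d, a, matrix(FALSE, 20, 20)), "empty mask")
})

test_that("ratio computation commutes with masking", {
  set.seed(7)
  m <- rect_mask(30, 30, 10, 20, 8, 22)
  d <- matrix(runif(900, 50, 150), 30, 30)
  a <- matrix(runif(900, 50, 150), 30, 30)
  r_full <- compute_ratio_image(d, a, matrix(TRUE, 30, 30))
  r_full[!m] <- NA
  r_masked <- compute_ratio_image(d, a, m)
  expect_equal(r_full, r_masked)
})

test_that("overlap linking keeps static and slowly translating cells intact", {
  m0 <- rect_mask(60, 30, 20, 35, 10, 20)
  static <- replicate(6, m0, simplify = FALSE)
  tr <- link_track(static)
  expect_length(tr$observations, 6)
  moving <- lapply(0:5, function(k) rect_mask(60, 30, 20 + 3 * k, 35 + 3 * k, 10, 20))
  tr2 <- link_track(moving)
  expect_length(tr2$observations, 6)
  expect_length(tr2$skipped_frames, 0)
})

test_that("zero-overlap links split the track with a warning, keeping the longest run", {
  jumpy <- c(lapply(0:3, function(k) rect_mask(90, 30, 10 + k, 20 + k, 5, 15)),
             lapply(0:1, function(k) rect_mask(90, 30, 70 + k, 80 + k, 5, 15)))
  expect_warning(tr <- link_track(jumpy), "split")
  expect_length(tr$observations, 4)
})

test_that("gaps of one frame are bridged", {
  masks <- lapply(0:4, function(k) rect_mask(60, 30, 20 + k, 35 + k, 10, 20))
  masks[3] <- list(NULL)
  tr <- link_track(masks)
  expect_length(tr$observations, 4)
  expect_identical(tr$skipped_frames, 3L)
})

test_that("kinematics recover configured speeds and loess is exact on polynomials", {
  # 3 px/frame at 0.21 um/px and 3 s frames = 0.21 um/s
  masks <- lapply(0:39, function(k) rect_mask(200, 40, 150 - 3 * k, 170 - 3 * k, 15, 25))
  tr <- link_track(masks, time_s = (0:39 - 10) * 3)
  tr <- compute_kinematics(tr)
  k <- tr$kinematics
  expect_equal(k$speed_um_s[-1], rep(0.21, 39), tolerance = 1e-12)
  expect_equal(k$speed_smoothed[-1], rep(0.21, 39), tolerance = 1e-9)
  expect_equal(k$signed_velocity_um_s[-1], rep(0.21, 39), tolerance = 1e-12)
  expect_identical(tr$direction0, 1)
  expect_equal(k$rel_length[k$time_s == 0], 1)
  expect_equal(k$rel_area, rep(1, 40))
  # stationary cell
  tr0 <- compute_kinematics(link_track(replicate(12, masks[[1]], simplify = FALSE),
                                       time_s = (0:11) * 3))
  expect_equal(tr0$kinematics$speed_um_s[-1], rep(0, 11))
  expect_equal(tr0$kinematics$speed_smoothed[-1], rep(0, 11), tolerance = 1e-9)
})

test_that("loess smoothing reproduces a linear speed trend to 1e-9", {
  # quadratic displacement -> linearly increasing step size
  offs <- cumsum(c(0, 1:15))
  masks <- lapply(offs, function(o) rect_mask(250, 40, 180 - o, 200 - o, 15, 25))
  tr <- compute_kinematics(link_track(masks, time_s = (seq_along(offs) - 2) * 3))
  k <- tr$kinematics
  expect_equal(k$speed_smoothed[-1], k$speed_um_s[-1], tolerance = 1e-9)
})

test_that("rear targeting follows the angle geometry", {
  m <- rect_mask(40, 20, 10, 30, 8, 12)
  # moving up: rear (180 deg) is the bottom-most boundary pixel
  rear <- locate_rear_target(m, 1, 180)
  expect_equal(unname(rear["row"]), 30)
  front <- locate_rear_target(m, 1, 0)
  expect_equal(unname(front["row"]), 10)
  expect_error(locate_rear_target(m, 0), "zero movement")
  # circle: returned point lies a radius away from the centroid at any angle
  dm <- disc_mask(41, 41, 21, 21, 12)
  for (ang in c(0, 45, 90, 135, 180, 270)) {
    p <- locate_rear_target(dm, 1, ang)
    d <- sqrt((p["row"] - 21)^2 + (p["col"] - 21)^2)
    expect_lt(abs(d - 12), 1.0)
  }
})
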