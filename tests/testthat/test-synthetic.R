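# Synthetic microscopy generator: determinism, kinetics realization,
# rendering equations.

test_that("zero baseline speed keeps the centroid fixed", {
  kin <- cell_kinetics("no_response", baseline_speed_um_s = 0)
  tr <- simulate_cell_track(kin, n_frames = 20, build_images = FALSE)
  expect_equal(diff(range(tr$centroid_row)), 0)
  expect_equal(diff(range(tr$centroid_col)), 0)
})

test_that("a no_response cell stays at baseline throughout", {
  tr <- simulate_cell_track(cell_kinetics("no_response"), n_frames = 61,
                            build_images = FALSE)$traces
  expect_equal(tr$rear, rep(1.0, 61))
  expect_equal(tr$front, rep(1.25, 61))
  expect_equal(diff(range(tr$velocity_um_s)), 0)
})

test_that("reversed kinetics realize the configured event schedule", {
  # dense grid so every crossing is bracketed tightly; the detector is the
  # analysis-side path, the generator the forward path
  kin <- cell_kinetics("reversed")
  t <- seq(-63, 117, by = 0.5)
  tr <- kinetics_traces(kin, t)
  ev <- detect_events(t, tr$front, tr$rear, tr$velocity_um_s, cfg0)
  expect_equal(ev$t_rear_response_s, 6, tolerance = 1e-9)
  expect_equal(ev$t_front_response_s, 15, tolerance = 1e-9)
  expect_equal(ev$t_stall_s, 27, tolerance = 1e-9)
  expect_equal(ev$t_crosspoint_s, 51, tolerance = 1e-9)
})

test_that("front and rear profile means intersect at the cross-point frame", {
  # cross-point at 51 s with 3 s frames: the sign of front - rear flips
  # across sample 17 post-stimulus
  tr <- simulate_cell_track(cell_kinetics("reversed", crosspoint_time_s = 51),
                            n_frames = 61, build_images = FALSE)$traces
  d <- tr$front - tr$rear
  i51 <- which(tr$time_s == 51)
  expect_true(d[i51 - 1] > 0)
  expect_equal(d[i51], 0, tolerance = 1e-12)
  expect_true(d[i51 + 1] < 0)
})

test_that("invalid class labels and non-ordered schedules error", {
  expect_error(cell_kinetics("wiggler"), "invalid class label")
  expect_error(cell_kinetics("reversed", stall_time_s = 60, crosspoint_time_s = 51),
               "ordered")
})

test_that("rendering reproduces activity exactly in the noise-free flat-field limit", {
  sc <- simulate_scene("reversed", seed = 4, n_frames = 10)
  st <- sc$frames
  for (i in c(1, 5, 10)) {
    m <- sc$track$masks[[i]]
    ratio <- (st$ch2[[i]] - 100)[m] / (st$ch1[[i]] - 100)[m]
    expect_equal(ratio, sc$track$activity_imgs[[i]][m], tolerance = 1e-12)
  }
})

test_that("uniform activity renders ratio exactly 1 on every mask pixel", {
  kin <- cell_kinetics("no_response", front_rear_ratio0 = 1)
  trk <- simulate_cell_track(kin, n_frames = 3)
  st <- render_frames(trk)
  m <- trk$masks[[2]]
  expect_equal((st$ch2[[2]] - 100)[m] / (st$ch1[[2]] - 100)[m],
               rep(1, sum(m)), tolerance = 1e-12)
})

test_that("a linear acceptor bias field shows up multiplicatively in the ratio", {
  nr <- 320; nc <- 64
  bias <- matrix(rep(seq(0.9, 1.1, length.out = nr), nc), nr, nc)
  acq <- acquisition_params(ratio_bias_field = bias)
  kin <- cell_kinetics("no_response", front_rear_ratio0 = 1)
  trk <- simulate_cell_track(kin, acq, n_frames = 3)
  st <- render_frames(trk, acq)
  m <- trk$masks[[1]]
  ratio <- (st$ch2[[1]] - 100) / (st$ch1[[1]] - 100)
  expect_equal(ratio[m], bias[m], tolerance = 1e-12)
})

test_that("rendering is bit-identical for identical (params, seed)", {
  acq <- acquisition_params(noise = list(gaussian_sd = 50, poisson = TRUE))
  a <- simulate_scene("medium", acq = acq, seed = 11, n_frames = 5)
  b <- simulate_scene("medium", acq = acq, seed = 11, n_frames = 5)
  expect_identical(a$frames$ch1, b$frames$ch1)
  expect_identical(a$frames$ch2, b$frames$ch2)
  c <- simulate_scene("medium", acq = acq, seed = 12, n_frames = 5)
  expect_false(identical(a$frames$ch1, c$frames$ch1))
})

test_that("cohorts draw labels deterministically and per-cell seeds rehash", {
  co <- simulate_cohort(c(reversed = 1), n_cells = 5, n_frames = 5,
                        seed = 3, render = FALSE)
  expect_length(co, 5)
  expect_true(all(vapply(co, function(s) s$class_label, "") == "reversed"))
  one <- simulate_cohort(c(medium = 1), n_cells = 1, n_frames = 5, seed = 8)
  expect_identical(attr(one, "master_seed"), 8L)
  # the same master seed reproduces the same cells
  co2 <- simulate_cohort(c(reversed = 1), n_cells = 5, n_frames = 5,
                         seed = 3, render = FALSE)
  expect_identical(vapply(co, `[[`, 1L, "seed"), vapply(co2, `[[`, 1L, "seed"))
})

test_that("realized class fractions stay within binomial error of the mix", {
  mix <- default_class_mix()
  n <- 400
  co <- simulate_cohort(mix, n_cells = n, n_frames = 2, seed = 21,
                        render = FALSE)
  lab <- vapply(co, function(s) s$class_label, "")
  for (cl in names(mix)) {
    p <- mix[[cl]]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(lab == cl) - p), 4 * se)
  }
})

test_that("degenerate cohort requests error", {
  expect_error(simulate_cohort(c(reversed = 1), n_cells = 0), "n_cells")
  expect_error(simulate_cohort(c(reversed = 0.5), n_cells = 3), "sum to 1")
  expect_error(simulate_cohort(c(oops = 1), n_cells = 3), "unknown class")
})

test_that("tracks that leave the field are rejected at render scale", {
  acq <- acquisition_params(field_shape = c(128, 64))
  expect_error(simulate_cell_track(cell_kinetics("no_response"), acq,
                                   n_frames = 61),
               "outside field")
})
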