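# Subcellular regions, activity quantification, profiles, kymographs.

test_that("edge regions saturate to the whole mask on small cells", {
  m <- rect_mask(60, 60, 11, 30, 11, 50)   # exactly 800 px
  rg <- edge_regions(m, 1, 800)
  expect_identical(rg$front_mask, m)
  expect_identical(rg$rear_mask, m)
  m2 <- rect_mask(30, 30, 5, 14, 5, 14)     # 100 px < 800
  expect_warning(rg2 <- edge_regions(m2, 1, 800), "below region size")
  expect_identical(rg2$front_mask, m2)
})

test_that("edge regions equal the brute-force distance-sort oracle", {
  # vertical bar: 200 rows x 10 cols
  bar <- rect_mask(220, 20, 11, 210, 6, 15)
  rg <- edge_regions(bar, 1, 800)
  front_pt <- locate_rear_target(bar, 1, 0)
  rear_pt <- locate_rear_target(bar, 1, 180)
  expect_identical(rg$front_mask, oracle_region(bar, front_pt, 800))
  expect_identical(rg$rear_mask, oracle_region(bar, rear_pt, 800))
  # the front cap sits at the top of the bar, the rear cap at the bottom
  expect_lt(max(which(rowSums(rg$front_mask) > 0)), 110)
  expect_gt(min(which(rowSums(rg$rear_mask) > 0)), 120)
  # irregular blobs up to 5000 px, several seeds
  for (s in 1:4) {
    set.seed(s)
    blob <- disc_mask(90, 70, 40 + s, 35, 26 + s)  # up to ~3.3k px
    blob[sample(which(blob), 150)] <- FALSE        # roughen the shape
    rgb_ <- edge_regions(blob, -1, 800)
    fp <- locate_rear_target(blob, -1, 0)
    rp <- locate_rear_target(blob, -1, 180)
    expect_identical(rgb_$front_mask, oracle_region(blob, fp, 800))
    expect_identical(rgb_$rear_mask, oracle_region(blob, rp, 800))
  }
})

test_that("middle region is the central third of the axial extent", {
  bar <- rect_mask(100, 20, 11, 70, 6, 15)   # rows 11..70
  rg <- edge_regions(bar, 1, 100)
  mid_rows <- which(rowSums(rg$middle_mask) > 0)
  expect_identical(mid_rows, 31:50)
})

test_that("region activity is the ratio of sums with undefined pixels excluded", {
  m <- rect_mask(40, 30, 1, 40, 1, 20)
  act <- matrix(1, 40, 30); act[1:20, ] <- 2   # front half 2.0 (top), rear 1.0
  p <- fret_pair(m, act)
  rg <- edge_regions(m, 1, 200)
  v <- region_activity(p$donor, p$acceptor, rg, m, cfg0)
  expect_equal(unname(v["front"]), 2)
  expect_equal(unname(v["rear"]), 1)
  # acceptor = donor everywhere -> all regions 1.0
  v1 <- region_activity(p$donor, p$donor, rg, m, cfg0)
  expect_equal(unname(v1), rep(1, 4))
  # a single undefined pixel is excluded, matching a brute-force sum
  d2 <- p$donor; a2 <- p$acceptor
  d2[5, 5] <- NA
  v2 <- region_activity(d2, a2, rg, m, cfg0)
  sel <- rg$front_mask; sel[5, 5] <- FALSE
  expect_equal(unname(v2["front"]), sum(a2[sel]) / sum(d2[sel] , na.rm = TRUE))
})

test_that("ratio-of-sums activity is invariant to common channel rescaling", {
  set.seed(3)
  m <- disc_mask(60, 60, 30, 30, 20)
  d <- matrix(runif(3600, 50, 100), 60, 60); d[!m] <- NA
  a <- matrix(runif(3600, 50, 100), 60, 60); a[!m] <- NA
  rg <- edge_regions(m, 1, 300)
  v1 <- region_activity(d, a, rg, m, cfg0)
  v2 <- region_activity(d * 3.7, a * 3.7, rg, m, cfg0)
  expect_equal(v1, v2, tolerance = 1e-12)
})

test_that("normalized region signal sums to the stated fractions", {
  m <- rect_mask(40, 40, 1, 40, 1, 20)      # 800 px cell
  rg <- edge_regions(m, 1, 200)             # front region = 25% of the cell
  ch <- matrix(0, 40, 40); ch[m] <- 5
  fr <- normalized_region_signal(ch, rg, m)
  expect_equal(unname(fr["front"]), 0.25)
  expect_equal(unname(fr["whole"]), 1)
  # all signal concentrated in the rear region
  ch2 <- matrix(0, 40, 40); ch2[rg$rear_mask] <- 3; ch2[!m] <- NA
  ch2[m & !rg$rear_mask] <- 0
  fr2 <- normalized_region_signal(ch2, rg, m)
  expect_equal(unname(fr2["rear"]), 1)
  # random image equals brute-force sums
  set.seed(9)
  ch3 <- matrix(runif(1600), 40, 40); ch3[!m] <- NA
  fr3 <- normalized_region_signal(ch3, rg, m)
  expect_equal(unname(fr3["middle"]),
               sum(ch3[rg$middle_mask]) / sum(ch3[m]))
  expect_true(all(fr3 >= 0 & fr3 <= 1))
})

test_that("1D profiles report per-row values relative to the centroid", {
  m <- rect_mask(50, 30, 11, 40, 11, 20)
  act <- matrix(1, 50, 30); act[11:25, ] <- 2
  p <- fret_pair(m, act)
  pr <- profile_1d(p$donor, p$acceptor, m, cfg0)
  expect_identical(nrow(pr), 30L)            # profile length = row extent
  expect_equal(pr$value[pr$row <= 25], rep(2, 15))
  expect_equal(pr$value[pr$row > 25], rep(1, 15))
  expect_equal(mean(pr$offset), 0)
  # uniform ratio -> constant profile; single-channel mode -> row means
  pr1 <- profile_1d(p$donor, p$donor, m, cfg0)
  expect_equal(pr1$value, rep(1, 30))
  pr2 <- profile_1d(p$donor, mask = m, config = cfg0)
  expect_equal(pr2$value, rep(500, 30))
})

test_that("profile resampling honors the smoothing-parameter convention", {
  x <- 1:20
  # constant profile -> constant output at any p
  for (p in c(0, 0.3, 0.5, 1))
    expect_equal(normalize_profile(x, rep(2.2, 20), 50, p), rep(2.2, 50),
                 tolerance = 1e-9)
  # exactly linear profile -> linear output for every p
  y <- 0.5 + 0.04 * x
  for (p in c(0, 0.3, 0.5, 1)) {
    out <- normalize_profile(x, y, 37, p)
    xo <- seq(1, 20, length.out = 37)
    expect_equal(out, 0.5 + 0.04 * xo, tolerance = 1e-8)
  }
  # p = 1 interpolates a cubic exactly at the knots
  yc <- 0.1 * x^3 - x^2 + 5
  out1 <- normalize_profile(x, yc, 20, 1)
  expect_equal(out1, yc, tolerance = 1e-9)
  expect_error(normalize_profile(1:3, 1:3, 10), "at least 4")
})

test_that("kymographs average cells and conserve the mean", {
  a <- matrix(1.1, 40, 8); b <- matrix(1.3, 40, 8)
  k <- build_kymograph(list(a, b))
  expect_equal(k$matrix, matrix(1.2, 40, 8))
  expect_identical(k$n_cells, rep(2L, 8))
  # one static cell -> all columns identical
  set.seed(4)
  prof <- matrix(rep(runif(40, 1, 1.5), 8), 40, 8)
  k1 <- build_kymograph(list(prof))
  expect_true(all(apply(k1$matrix, 1, function(r) diff(range(r)) == 0)))
  # difference kymograph of identical cohorts is zero
  expect_equal(build_kymograph(list(a))$matrix - build_kymograph(list(a))$matrix,
               matrix(0, 40, 8))
  # conservation: grand mean equals mean of per-cell profile means
  cells <- lapply(1:5, function(i) matrix(runif(40 * 8, 1, 2), 40, 8))
  kk <- build_kymograph(cells)
  expect_equal(mean(kk$matrix), mean(vapply(cells, mean, 1)), tolerance = 1e-9)
})

test_that("event order is insensitive to the region penetration depth", {
  # same polarized reversing cell quantified with 400- and 800-px regions
  trk <- simulate_cell_track(cell_kinetics("reversed"), n_frames = 61, seed = 2)
  orders <- lapply(c(400, 800), function(sz) {
    cfg <- polarflip_config(region_size_px = sz)
    donor <- lapply(trk$masks, function(m) { x <- matrix(NA_real_, 320, 64); x[m] <- 500; x })
    acceptor <- lapply(seq_along(trk$masks), function(i) {
      x <- trk$activity_imgs[[i]] * 500; x })
    s <- region_activity_series(donor, acceptor, trk$masks, trk$time_s, 1, cfg)
    ev <- detect_events(trk$time_s, s$front, s$rear, trk$traces$velocity_um_s, cfg)
    order(c(ev$t_rear_response_s, ev$t_front_response_s, ev$t_stall_s,
            ev$t_crosspoint_s))
  })
  expect_identical(orders[[1]], orders[[2]])
  expect_identical(orders[[1]], 1:4)
})
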