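test_that("ROIs split the test area at the midline, social side first", {
  g <- rectangular_chamber(25, 75, 8, 75, "left")
  rois <- build_rois(g)
  expect_equal(c(rois$social$xmin, rois$social$xmax), c(0, 12.5))
  expect_equal(c(rois$social$ymin, rois$social$ymax), c(0, 75))
  expect_equal(c(rois$antisocial$xmin, rois$antisocial$xmax), c(12.5, 25))
  # mirrored for stimulus on the right
  rois_r <- build_rois(rectangular_chamber(25, 75, 8, 75, "right"))
  expect_equal(c(rois_r$social$xmin, rois_r$social$xmax), c(12.5, 25))
  # 8 wpf chamber gives 25 x 75 halves
  rois8 <- build_rois(rectangular_chamber(50, 75, 16, 75, "left"))
  expect_equal(rois8$social$xmax, 25)
  expect_error(build_rois(circular_arena(700)), "rectangular")
})

test_that("the two ROIs partition the test area, midline counting social", {
  for (side in c("left", "right")) {
    g <- rectangular_chamber(25, 75, 8, 75, side)
    rois <- build_rois(g)
    set.seed(1)
    x <- c(runif(500, 0, 25), 12.5, 0, 25)  # include boundary points
    y <- c(runif(500, 0, 75), 10, 0, 75)
    in_s <- shoalkit:::roi_contains(rois$social, x, y)
    in_a <- shoalkit:::roi_contains(rois$antisocial, x, y)
    expect_true(all(xor(in_s, in_a)))  # exactly one ROI each
    expect_true(in_s[length(x) - 2])   # midline point is social
  }
})

test_that("time-in-ROI percentages count tracked frames only", {
  g <- rectangular_chamber(25, 75, 8, 75, "left")
  rois <- build_rois(g)
  # stationary inside the social half
  ts <- trajectory_set(cbind(rep(5, 10)), cbind(rep(10, 10)), 20, g)
  expect_equal(fraction_time_in_roi(ts, rois$social), 100)
  expect_equal(fraction_time_in_roi(ts, rois$antisocial), 0)
  # alternating 1 frame in / 1 frame out over an even window
  ts2 <- trajectory_set(cbind(rep(c(5, 20), 5)), cbind(rep(10, 10)), 20, g)
  expect_equal(fraction_time_in_roi(ts2, rois$social), 50)
  # dropouts drop out of both numerator and denominator
  x <- rep(c(5, 20), 5); x[c(2, 4)] <- NA
  ts3 <- trajectory_set(cbind(x), cbind(rep(10, 10)), 20, g)
  expect_equal(fraction_time_in_roi(ts3, rois$social), 100 * 5 / 8)
  # all-missing window is undefined
  ts4 <- trajectory_set(cbind(c(NA, NA, 5)), cbind(c(NA, NA, 5)), 20, g)
  expect_error(fraction_time_in_roi(ts4, rois$social, c(0, 2)), "missing")
  # social + antisocial = 100 for gap-free trajectories
  p <- preference_sim_params(g, duration_s = 30, seed = 6)
  sim <- simulate_preference_fish(p)
  expect_equal(fraction_time_in_roi(sim, rois$social) +
                 fraction_time_in_roi(sim, rois$antisocial), 100)
})

test_that("scoring is invariant under mirror reflection of fish and stimulus", {
  gl <- rectangular_chamber(25, 75, 8, 75, "left")
  gr <- rectangular_chamber(25, 75, 8, 75, "right")
  p <- preference_sim_params(gl, bias_mm_s = 3, duration_s = 60, seed = 13)
  ts <- simulate_preference_fish(p)
  mirrored <- trajectory_set(25 - ts$x, ts$y, ts$frame_rate_hz, gr,
                             ts$fish_ids, ts$source_id)
  expect_equal(
    fraction_time_in_roi(mirrored, build_rois(gr)$social),
    fraction_time_in_roi(ts, build_rois(gl)$social)
  )
})

test_that("the exclusion threshold is 0.6 times the smallest group mean", {
  expect_equal(exclusion_threshold(c(10, 8, 12)), 4.8)
  expect_equal(exclusion_threshold(5), 3.0)
  expect_equal(exclusion_threshold(c(7, 7, 7)), 0.6 * 7)
  expect_error(exclusion_threshold(numeric(0)), "at least one")
  expect_error(exclusion_threshold(c(3, -1)), ">= 0")
})

test_that("assay scoring applies the protocol windows and the >= tie rule", {
  g <- rectangular_chamber(25, 75, 8, 75, "left")
  proto <- assay_protocol(habituation_s = 10, test_s = 12, analysis_last_s = 10)
  fps <- 20
  T <- 22 * fps
  # fish moves 0.25 mm per frame (5 mm/s) along y, stays at x = 5 (social)
  ts <- trajectory_set(cbind(rep(5, T)),
                       cbind(35 + 0.25 * ((seq_len(T) - 1) %% 2)), fps, g)
  r <- score_assay(ts, proto, threshold_mm_s = 5)  # exactly at threshold
  expect_true(r$included)                          # >= rule includes ties
  expect_equal(r$mean_speed_test, 5)
  expect_equal(r$percent_time_social, 100)
  r2 <- score_assay(ts, proto, threshold_mm_s = 5 + 1e-9)
  expect_false(r2$included)
  # stationary fish: speed 0, excluded under any positive threshold
  ts0 <- trajectory_set(cbind(rep(5, T)), cbind(rep(35, T)), fps, g)
  r0 <- score_assay(ts0, proto, threshold_mm_s = 0.1)
  expect_false(r0$included)
  expect_equal(r0$mean_speed_test, 0)
  # too-short trajectory errors
  short <- trajectory_set(cbind(rep(5, 10)), cbind(rep(35, 10)), fps, g)
  expect_error(score_assay(short, proto), "too short")
})

test_that("exclusion basis is configurable between phases", {
  g <- rectangular_chamber(25, 75, 8, 75, "left")
  proto <- assay_protocol(habituation_s = 2, test_s = 4, analysis_last_s = 3)
  fps <- 10
  # fast during habituation (1 mm/frame), frozen during test
  hab_T <- 2 * fps; test_T <- 4 * fps
  x <- c(seq(0, by = 0.5, length.out = hab_T), rep(10, test_T))
  ts <- trajectory_set(cbind(pmin(x, 24)), cbind(rep(35, hab_T + test_T)), fps, g)
  thr <- 1
  expect_false(score_assay(ts, proto, threshold_mm_s = thr,
                           exclusion_basis = "test")$included)
  expect_true(score_assay(ts, proto, threshold_mm_s = thr,
                          exclusion_basis = "habituation")$included)
  expect_false(score_assay(ts, proto, threshold_mm_s = thr,
                           exclusion_basis = "min")$included)
})
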