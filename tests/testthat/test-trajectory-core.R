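test_that("trajectory set construction enforces the basic invariants", {
  a <- circular_arena(700)
  expect_error(trajectory_set(matrix(0, 0, 1), matrix(0, 0, 1), 30, a),
               "at least one frame")
  expect_error(trajectory_set(matrix(0, 3, 0), matrix(0, 3, 0), 30, a),
               "at least one fish")
  expect_error(trajectory_set(matrix(0, 3, 2), matrix(0, 3, 2), 0, a),
               "positive")
  expect_error(trajectory_set(matrix(0, 3, 2), matrix(0, 4, 2), 30, a),
               "same shape")
  # a half-missing sample becomes fully missing
  ts <- trajectory_set(cbind(c(1, NA, 3)), cbind(c(1, 2, 3)), 30, a)
  expect_true(is.na(ts$y[2, 1]))
})

test_that("write/read round trip is the identity, including gaps", {
  p <- shared_motion_params_rho(0.6, n_fish = 4, duration_s = 3,
                                frame_rate_hz = 30, seed = 42)
  ts <- add_dropouts(simulate_shared_motion_shoal(p), rate = 0.1, seed = 5)
  path <- file.path(tempdir(), "roundtrip.csv")
  write_trajectories(ts, path)
  ts2 <- read_trajectories(path)
  expect_identical(ts2$fish_ids, ts$fish_ids)
  expect_equal(ts2$frame_rate_hz, ts$frame_rate_hz)
  expect_identical(unname(is.na(ts2$x)), unname(is.na(ts$x)))
  expect_equal(unname(ts2$x), unname(ts$x), tolerance = 1e-6)
  expect_equal(unname(ts2$y), unname(ts$y), tolerance = 1e-6)
  expect_equal(ts2$arena$diameter_mm, ts$arena$diameter_mm)
  unlink(c(path, shoalkit:::sidecar_path(path)))
})

test_that("malformed files are rejected with informative errors", {
  path <- file.path(tempdir(), "bad.csv")
  side <- shoalkit:::sidecar_path(path)
  meta <- list(frame_rate_hz = 30,
               arena = shoalkit:::arena_to_list(circular_arena(700)),
               source_id = "bad", fish_ids = c("a", "b"))
  jsonlite::write_json(meta, side, auto_unbox = TRUE)
  # fish 'a' has 3 frames, fish 'b' has 4
  writeLines(c("frame,fish_id,x_mm,y_mm",
               "0,a,1,1", "1,a,1,1", "2,a,1,1",
               "0,b,1,1", "1,b,1,1", "2,b,1,1", "3,b,1,1"), path)
  expect_error(read_trajectories(path), "inconsistent frame counts")
  # malformed coordinate names its line
  writeLines(c("frame,fish_id,x_mm,y_mm",
               "0,a,1,1", "1,a,oops,1",
               "0,b,1,1", "1,b,1,1"), path)
  expect_error(read_trajectories(path), "line 3.*oops")
  # no sidecar -> configuration error
  unlink(side)
  expect_error(read_trajectories(path), "sidecar")
  unlink(path)
})

test_that("gap filling interpolates short gaps only and never edits data", {
  a <- circular_arena(700)
  x <- cbind(c(0, NA, 2, 3, NA, NA, NA, NA, NA, NA, 10, NA))
  y <- cbind(c(0, NA, 2, 3, NA, NA, NA, NA, NA, NA, 10, NA))
  ts <- trajectory_set(x, y, 30, a)
  f <- fill_gaps(ts, max_gap_frames = 3)
  expect_equal(unname(f$x[2, 1]), 1)          # midpoint of (0,0)-(2,2)
  expect_equal(unname(f$y[2, 1]), 1)
  expect_true(all(is.na(f$x[5:10, 1])))       # 6-frame gap > max_gap retained
  expect_true(is.na(f$x[12, 1]))              # trailing gap retained
  present <- !is.na(ts$x)
  expect_equal(f$x[present], ts$x[present])   # originally present untouched
  # no gaps -> identity; max_gap 0 -> identity
  ts2 <- random_ts(3, 20, seed = 1)
  expect_equal(fill_gaps(ts2, 5)$x, ts2$x)
  expect_equal(fill_gaps(ts, 0)$x, ts$x)
})

test_that("mean swim speed follows the consecutive-step definition", {
  a <- rectangular_chamber()
  # stationary fish
  ts0 <- trajectory_set(cbind(rep(5, 10)), cbind(rep(5, 10)), 30, a)
  expect_equal(mean_swim_speed(ts0, 1), 0)
  # 1 mm per frame at 30 fps -> 30 mm/s
  ts1 <- trajectory_set(cbind(seq(0, 9)), cbind(rep(1, 10)), 30, a)
  expect_equal(mean_swim_speed(ts1, 1), 30)
  # 3 mm then 4 mm over 2 steps at 20 fps -> 70 mm/s
  ts2 <- trajectory_set(cbind(c(0, 3, 3)), cbind(c(0, 0, 4)), 20, a)
  expect_equal(mean_swim_speed(ts2, 1), 70)
  # pairs spanning a gap are dropped from numerator and denominator
  ts3 <- trajectory_set(cbind(c(0, 1, NA, 100)), cbind(rep(0, 4)), 30, a)
  expect_equal(mean_swim_speed(ts3, 1), 30)   # only the 0->1 step counts
  # undefined with < 2 tracked frames
  ts4 <- trajectory_set(cbind(c(1, NA, NA)), cbind(c(1, NA, NA)), 30, a)
  expect_error(mean_swim_speed(ts4, 1), "undefined")
})

test_that("speed is translation invariant and scales with frame rate", {
  ts <- random_ts(3, 60, fps = 30, seed = 7)
  shifted <- trajectory_set(ts$x + 123, ts$y - 45, 30, ts$arena)
  doubled <- trajectory_set(ts$x, ts$y, 60, ts$arena)
  for (j in 1:3) {
    v <- mean_swim_speed(ts, j)
    expect_equal(mean_swim_speed(shifted, j), v)
    expect_equal(mean_swim_speed(doubled, j), 2 * v)
  }
})

test_that("frame windows are half-open and zero-based", {
  a <- rectangular_chamber()
  ts <- trajectory_set(cbind(c(0, 1, 2, 10)), cbind(rep(0, 4)), 10, a)
  # window [0, 3) covers steps 0->1 and 1->2 only
  expect_equal(mean_swim_speed(ts, 1, c(0, 3)), 10)
  expect_error(mean_swim_speed(ts, 1, c(2, 2)), "empty|outside")
  expect_error(mean_swim_speed(ts, 1, c(0, 9)), "outside")
})
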