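test_that("the 3-4-5 three-fish configuration gives the hand-computed values", {
  ts <- static_ts(c(0, 3, 6), c(0, 4, 8), frames = 3)
  nd <- neighbor_distances(ts)
  expect_equal(nd$per_fish$nnd_mm, c(5, 5, 5))
  expect_equal(nd$per_fish$fnd_mm, c(10, 5, 10))
  expect_equal(nd$per_fish$iid_mm, c(7.5, 5, 7.5))
  expect_equal(unname(nd$shoal["nnd_mm"]), 5)
  expect_equal(unname(nd$shoal["iid_mm"]), 20 / 3)
  expect_equal(unname(nd$shoal["fnd_mm"]), 25 / 3)
  # pair-mean convention for the same configuration
  expect_equal(unname(nd$shoal["iid_pair_mm"]), mean(c(5, 10, 5)))
})

test_that("two fish collapse all three distances to their separation", {
  ts <- static_ts(c(0, 3), c(0, 4), frames = 2)
  nd <- neighbor_distances(ts)
  expect_equal(unname(nd$shoal[c("nnd_mm", "iid_mm", "fnd_mm")]), c(5, 5, 5))
  expect_error(neighbor_distances(static_ts(1, 1)), "at least 2")
})

test_that("nnd <= iid <= fnd holds per fish and frame, even with dropouts", {
  for (seed in 1:3) {
    ts <- random_ts(n_fish = 6, frames = 80, dropout = 0.1, seed = seed)
    fr <- neighbor_distances(ts, keep_frames = TRUE)$frames
    ok <- !is.na(fr$nnd)
    expect_true(all(fr$nnd[ok] <= fr$iid[ok] + 1e-12))
    expect_true(all(fr$iid[ok] <= fr$fnd[ok] + 1e-12))
  }
})

test_that("distances are translation invariant and scale with the data", {
  ts <- random_ts(n_fish = 5, frames = 60, seed = 4)
  shifted <- trajectory_set(ts$x + 50, ts$y - 30, 30, ts$arena)
  scaled <- trajectory_set(ts$x * 3, ts$y * 3, 30, ts$arena)
  nd <- neighbor_distances(ts)$shoal
  expect_equal(neighbor_distances(shifted)$shoal, nd)
  expect_equal(neighbor_distances(scaled)$shoal, 3 * nd)
  # variance explained: translation and uniform-scaling invariant
  ve <- variance_explained(assemble_trajectory_matrix(ts))$variance_explained
  expect_equal(
    variance_explained(assemble_trajectory_matrix(shifted))$variance_explained,
    ve)
  expect_equal(
    variance_explained(assemble_trajectory_matrix(scaled))$variance_explained,
    ve)
})

test_that("cumulative shoal distance sums per-fish path lengths", {
  expect_equal(cumulative_shoal_distance(static_ts(1:4, 1:4, frames = 5)), 0)
  # 20 fish each travelling 100 mm -> 2000 mm
  x <- sapply(1:20, function(i) seq(0, 100, length.out = 101) + i)
  ts <- trajectory_set(x, matrix(200, 101, 20), 30, circular_arena(700))
  expect_equal(cumulative_shoal_distance(ts), 2000)
  # rigid translation by d moves every fish d
  expect_equal(cumulative_shoal_distance(ts, method = "centroid"), 100)
  # gaps break the path: step across a gap is not counted
  xg <- cbind(c(0, 1, NA, 3, 4))
  tsg <- trajectory_set(xg, 0 * xg, 30, circular_arena(700))
  expect_equal(cumulative_shoal_distance(tsg), 2)
})

test_that("trajectory matrix assembly follows the 2N rule and drops gaps", {
  ts <- random_ts(n_fish = 3, frames = 10, seed = 5)
  m <- assemble_trajectory_matrix(ts)
  expect_equal(dim(m$matrix), c(6, 10))
  expect_equal(rownames(m$matrix)[1:3], c("fish01_x", "fish01_y", "fish02_x"))
  expect_equal(m$matrix[1, ], unname(ts$x[, 1]))
  expect_equal(m$matrix[4, ], unname(ts$y[, 2]))
  # 2 missing frames of 10 -> 6 x 8 with the mask recording which
  ts$x[c(3, 7), 2] <- NA; ts$y[c(3, 7), 2] <- NA
  ts2 <- trajectory_set(ts$x, ts$y, 30, ts$arena)
  m2 <- assemble_trajectory_matrix(ts2)
  expect_equal(dim(m2$matrix), c(6, 8))
  expect_equal(which(!m2$frames_retained), c(3, 7))
  # all frames gappy -> error
  ts$x[, 1] <- NA
  expect_error(assemble_trajectory_matrix(
    trajectory_set(ts$x, ts$y, 30, ts$arena)), "empty")
})

test_that("variance explained matches an independent singular-value route", {
  for (seed in 1:5) {
    set.seed(seed)
    M <- matrix(rnorm(6 * 50), 6, 50) + outer(rnorm(6), rnorm(50))
    ve <- variance_explained(M)$variance_explained
    expect_equal(ve, svd_variance_explained(M), tolerance = 1e-8)
  }
})

test_that("variance explained hits its structural bounds", {
  # identical moving fish: rank-2 covariance, VE exactly 1
  base <- random_ts(1, 40, seed = 6)
  x <- matrix(base$x[, 1], 40, 8); y <- matrix(base$y[, 1], 40, 8)
  ts <- trajectory_set(x, y, 30, circular_arena(700))
  ve <- variance_explained(assemble_trajectory_matrix(ts))
  expect_equal(ve$variance_explained, 1.0, tolerance = 1e-9)
  expect_true(all(ve$eigenvalues >= 0))
  # lower bound 1/N, upper bound 1 on arbitrary data
  ts2 <- random_ts(5, 100, seed = 7)
  v2 <- variance_explained(assemble_trajectory_matrix(ts2))$variance_explained
  expect_gte(v2, 1 / 5)
  expect_lte(v2, 1)
  # all-stationary shoal: statistic undefined
  expect_error(variance_explained(
    assemble_trajectory_matrix(static_ts(1:3, 1:3, frames = 5))), "stationary")
})

test_that("shoal_metrics aggregates one consistent record per shoal", {
  # rigid translation: constant neighbor distances, VE = 1
  t_seq <- seq(0, 50, length.out = 60)
  x <- outer(t_seq, rep(1, 4)) + rep(c(0, 10, 20, 30), each = 60)
  y <- outer(t_seq, rep(1, 4)) + 300
  ts <- trajectory_set(matrix(x, 60, 4), matrix(y, 60, 4), 30,
                       circular_arena(700))
  sm <- shoal_metrics(ts)
  expect_equal(sm$variance_explained_2, 1.0, tolerance = 1e-9)
  expect_equal(sm$nnd_mm, 10)
  expect_equal(sm$n_fish, 4)
  expect_equal(sm$frames_used, 60)
  expect_true(sm$nnd_mm <= sm$iid_mm && sm$iid_mm <= sm$fnd_mm)
  # higher coordination -> higher VE at matched total motion
  lo <- shoal_metrics(simulate_shared_motion_shoal(
    shared_motion_params_rho(0, n_fish = 10, duration_s = 120, seed = 8)))
  hi <- shoal_metrics(simulate_shared_motion_shoal(
    shared_motion_params_rho(0.9, n_fish = 10, duration_s = 120, seed = 8)))
  expect_gt(hi$variance_explained_2, lo$variance_explained_2)
  expect_equal(hi$cumulative_distance_mm / lo$cumulative_distance_mm, 1,
               tolerance = 0.1)
})

test_that("mixed-movie control is exact at k_same = n_total and needs movies", {
  recs <- lapply(1:4, function(s) simulate_shared_motion_shoal(
    shared_motion_params_rho(0.7, n_fish = 5, duration_s = 30, seed = s)))
  true_ve <- variance_explained(
    assemble_trajectory_matrix(recs[[1]]))$variance_explained
  ctl <- mixed_shoal_control(recs, k_same = 5, n_total = 5,
                             replicates = 3, seed = 1)
  # any focal recording reproduces its own VE; sd over replicates is the
  # spread across focal movies, not noise
  expect_equal(ctl$k_same, 5L)
  ves <- vapply(recs, function(r) variance_explained(
    assemble_trajectory_matrix(r))$variance_explained, numeric(1))
  expect_true(ctl$mean_ve >= min(ves) - 1e-12 && ctl$mean_ve <= max(ves) + 1e-12)
  expect_error(mixed_shoal_control(recs, k_same = 0, n_total = 5),
               "distinct recordings", fixed = FALSE)
  expect_error(mixed_shoal_control(recs[1], k_same = 2), "at least 2")
})
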