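#' Shared-motion shoal generator parameters
#'
#' The shared-motion model writes the position of fish i at frame t as
#' `center + c(t) + e_i(t)`, where the shoal-level process `c` and the
#' per-fish idiosyncratic processes `e_i` are independent stationary
#' mean-reverting (discrete Ornstein-Uhlenbeck) random walks, per coordinate,
#' with stationary SDs `sigma_shared_mm` and `sigma_idio_mm`. The
#' coordination level is
#' `rho = sigma_shared^2 / (sigma_shared^2 + sigma_idio^2)` in `[0, 1]`.
#'
#' This model is chosen because the trajectory-matrix polarization statistic
#' has a closed form under it: per axis the N x N covariance is
#' `sigma_shared^2 * J + sigma_idio^2 * I`, whose top eigenvalue is
#' `N * sigma_shared^2 + sigma_idio^2`, so the population variance explained
#' by the top two of the 2N eigenvalues is `rho + (1 - rho) / N`
#' (see [expected_variance_explained()]).
#'
#' @param n_fish number of fish (>= 2); 20 matches the shoaling assay.
#' @param duration_s recording length in seconds; 1800 (30 min) matches the
#'   assay.
#' @param frame_rate_hz frames per second; 30 matches the assay.
#' @param sigma_shared_mm stationary per-coordinate SD of the shared centroid
#'   process, mm.
#' @param sigma_idio_mm stationary per-coordinate SD of each fish's own
#'   process, mm.
#' @param relaxation_s mean-reversion (relaxation) time of the OU processes,
#'   seconds. The default 0.1 s keeps the number of effectively independent
#'   frames in a 30-min recording large relative to the 40 matrix rows, so
#'   the empirical variance explained matches the closed form tightly; see
#'   the methods vignette.
#' @param arena an [ArenaGeometry][rectangular_chamber]; positions are
#'   centered on it.
#' @param reflect clip/reflect positions into the arena? Off by default so
#'   the closed-form covariance holds exactly.
#' @param seed integer seed; a single seed deterministically drives the
#'   shared process and every per-fish process.
#' @return A `SharedMotionParams` object.
#' @export
shared_motion_params <- function(n_fish = 20, duration_s = 1800,
                                 frame_rate_hz = 30,
                                 sigma_shared_mm = 30, sigma_idio_mm = 30,
                                 relaxation_s = 0.1,
                                 arena = circular_arena(700),
                                 reflect = FALSE, seed = NULL) {
  if (n_fish < 2) stopf("n_fish must be >= 2")
  if (sigma_shared_mm < 0 || sigma_idio_mm < 0) stopf("sigmas must be >= 0")
  if (sigma_shared_mm == 0 && sigma_idio_mm == 0) {
    stopf("at least one of sigma_shared_mm, sigma_idio_mm must be positive")
  }
  if (relaxation_s <= 0) stopf("relaxation_s must be positive")
  T <- round(duration_s * frame_rate_hz)
  if (T < 2) stopf("duration_s * frame_rate_hz must be >= 2")
  structure(
    list(
      n_fish = as.integer(n_fish), duration_s = duration_s,
      frame_rate_hz = frame_rate_hz,
      sigma_shared_mm = sigma_shared_mm, sigma_idio_mm = sigma_idio_mm,
      relaxation_s = relaxation_s, arena = arena, reflect = reflect,
      seed = seed
    ),
    class = "SharedMotionParams"
  )
}

#' @rdname shared_motion_params
#' @param rho coordination level in `[0, 1]`.
#' @param sigma_total_mm total per-coordinate stationary SD, split between
#'   shared and idiosyncratic components according to `rho`.
#' @param ... passed on to [shared_motion_params()].
#' @export
shared_motion_params_rho <- function(rho, sigma_total_mm = 30, ...) {
  if (rho < 0 || rho > 1) stopf("rho must lie in [0, 1]")
  shared_motion_params(
    sigma_shared_mm = sqrt(rho) * sigma_total_mm,
    sigma_idio_mm = sqrt(1 - rho) * sigma_total_mm,
    ...
  )
}

#' @rdname shared_motion_params
#' @param p a `SharedMotionParams` object.
#' @export
coordination <- function(p) {
  stopifnot(inherits(p, "SharedMotionParams"))
  s2 <- p$sigma_shared_mm^2
  i2 <- p$sigma_idio_mm^2
  s2 / (s2 + i2)
}

# stationary AR(1) series of length n with lag-1 coefficient a and
# stationary SD sd, started from its stationary distribution
ou_series <- function(n, a, sd) {
  if (sd == 0) return(numeric(n))
  z0 <- rnorm(1, 0, sd)
  innov <- rnorm(n, 0, sd * sqrt(1 - a^2))
  as.numeric(stats::filter(innov, a, method = "recursive", init = z0))
}

#' Simulate a shoal under the shared-motion model
#'
#' Generates a [TrajectorySet][trajectory_set] whose coordination level is
#' known by construction; see [shared_motion_params()] for the model.
#' Reproducible for a fixed seed.
#'
#' @param p a [SharedMotionParams][shared_motion_params] object.
#' @return A `TrajectorySet` with `p$n_fish` fish.
#' @examples
#' p <- shared_motion_params_rho(0.5, n_fish = 5, duration_s = 2, seed = 1)
#' ts <- simulate_shared_motion_shoal(p)
#' @export
simulate_shared_motion_shoal <- function(p) {
  stopifnot(inherits(p, "SharedMotionParams"))
  T <- round(p$duration_s * p$frame_rate_hz)
  N <- p$n_fish
  a <- exp(-1 / (p$relaxation_s * p$frame_rate_hz))
  ctr <- arena_center(p$arena)
  with_rng_seed(p$seed, {
    cx <- ou_series(T, a, p$sigma_shared_mm)
    cy <- ou_series(T, a, p$sigma_shared_mm)
    x <- matrix(NA_real_, T, N)
    y <- matrix(NA_real_, T, N)
    for (i in seq_len(N)) {
      x[, i] <- ctr[1] + cx + ou_series(T, a, p$sigma_idio_mm)
      y[, i] <- ctr[2] + cy + ou_series(T, a, p$sigma_idio_mm)
    }
    if (p$reflect && is_circular(p$arena)) {
      r <- p$arena$diameter_mm / 2
      d <- sqrt((x - ctr[1])^2 + (y - ctr[2])^2)
      over <- which(d > r)
      if (length(over)) {
        # fold radially back inside (single reflection; excursions beyond 2r
        # are clamped to the wall)
        fac <- pmax(2 * r - d[over], 0) / d[over]
        x[over] <- ctr[1] + (x[over] - ctr[1]) * fac
        y[over] <- ctr[2] + (y[over] - ctr[2]) * fac
      }
    }
    trajectory_set(x, y, p$frame_rate_hz, p$arena,
                   source_id = sprintf("shared-motion-rho%.3f", coordination(p)))
  })
}

#' Population variance explained under the shared-motion model
#'
#' Closed form for the fraction of total variance of the 2N-dimensional
#' trajectory covariance captured by its top two eigenvalues:
#' `rho + (1 - rho) / n_fish`, where `rho` is the coordination level.
#' Fully coordinated shoals (`rho = 1`) give 1; independent fish (`rho = 0`)
#' give `1 / n_fish`.
#'
#' @param p a [SharedMotionParams][shared_motion_params] object.
#' @return A fraction in `[1/n_fish, 1]`.
#' @export
expected_variance_explained <- function(p) {
  rho <- coordination(p)
  rho + (1 - rho) / p$n_fish
}

#' Zonal (repulsion/alignment/attraction) shoal generator
#'
#' An agent-based generator for qualitatively realistic shoals: each fish
#' turns away from neighbors inside the repulsion zone; otherwise it averages
#' the headings of neighbors inside the alignment zone and steers toward
#' neighbors in the shell between the alignment and attraction radii, with
#' Gaussian angular noise, moving at constant speed inside a reflecting
#' circular boundary.
#'
#' @param n_fish number of fish (>= 2).
#' @param r_repulsion_mm,r_alignment_mm,r_attraction_mm zone radii, mm,
#'   strictly increasing.
#' @param speed_mm_s constant swim speed, mm/s.
#' @param turning_noise_sd angular noise SD per frame, radians.
#' @param frame_rate_hz,duration_s frame rate and duration.
#' @param arena a circular [ArenaGeometry][circular_arena].
#' @param seed integer seed.
#' @return A `ZonalParams` object.
#' @export
zonal_params <- function(n_fish = 20, r_repulsion_mm = 15,
                         r_alignment_mm = 60, r_attraction_mm = 250,
                         speed_mm_s = 50, turning_noise_sd = 0.25,
                         frame_rate_hz = 30, duration_s = 60,
                         arena = circular_arena(700), seed = NULL) {
  if (n_fish < 2) stopf("n_fish must be >= 2")
  radii <- c(r_repulsion_mm, r_alignment_mm, r_attraction_mm)
  if (any(radii <= 0) || any(diff(radii) <= 0)) {
    stopf("zone radii must be positive and strictly increasing")
  }
  if (speed_mm_s <= 0 || turning_noise_sd < 0) {
    stopf("speed must be positive and noise SD non-negative")
  }
  if (!is_circular(arena)) stopf("the zonal generator needs a circular arena")
  structure(
    list(
      n_fish = as.integer(n_fish),
      r_repulsion_mm = r_repulsion_mm, r_alignment_mm = r_alignment_mm,
      r_attraction_mm = r_attraction_mm, speed_mm_s = speed_mm_s,
      turning_noise_sd = turning_noise_sd, frame_rate_hz = frame_rate_hz,
      duration_s = duration_s, arena = arena, seed = seed
    ),
    class = "ZonalParams"
  )
}

#' @rdname zonal_params
#' @param p a `ZonalParams` object.
#' @return `simulate_zonal_shoal()`: a [TrajectorySet][trajectory_set].
#' @export
simulate_zonal_shoal <- function(p) {
  stopifnot(inherits(p, "ZonalParams"))
  T <- round(p$duration_s * p$frame_rate_hz)
  N <- p$n_fish
  dt <- 1 / p$frame_rate_hz
  ctr <- arena_center(p$arena)
  R <- p$arena$diameter_mm / 2
  step <- p$speed_mm_s * dt
  with_rng_seed(p$seed, {
    # dispersed start: uniform in the disc, uniform headings
    rr <- R * 0.9 * sqrt(runif(N))
    aa <- runif(N, 0, 2 * pi)
    px <- ctr[1] + rr * cos(aa)
    py <- ctr[2] + rr * sin(aa)
    theta <- runif(N, 0, 2 * pi)
    x <- matrix(NA_real_, T, N)
    y <- matrix(NA_real_, T, N)
    x[1, ] <- px; y[1, ] <- py
    for (t in 2:T) {
      dx <- outer(px, px, "-")  # dx[i,j] = px[i] - px[j]
      dy <- outer(py, py, "-")
      D <- sqrt(dx^2 + dy^2)
      diag(D) <- Inf
      des <- theta
      for (i in seq_len(N)) {
        rep_j <- which(D[i, ] < p$r_repulsion_mm)
        if (length(rep_j)) {
          vx <- sum(dx[i, rep_j]); vy <- sum(dy[i, rep_j])  # away from them
          if (vx != 0 || vy != 0) des[i] <- atan2(vy, vx)
        } else {
          al_j <- which(D[i, ] < p$r_alignment_mm)
          at_j <- which(D[i, ] >= p$r_alignment_mm & D[i, ] < p$r_attraction_mm)
          vx <- 0; vy <- 0
          if (length(al_j)) {
            vx <- vx + mean(cos(theta[al_j]))
            vy <- vy + mean(sin(theta[al_j]))
          }
          if (length(at_j)) {
            wx <- -mean(dx[i, at_j]); wy <- -mean(dy[i, at_j])  # toward them
            nw <- sqrt(wx^2 + wy^2)
            if (nw > 0) { vx <- vx + wx / nw; vy <- vy + wy / nw }
          }
          if (vx != 0 || vy != 0) des[i] <- atan2(vy, vx)
        }
      }
      theta <- des + rnorm(N, 0, p$turning_noise_sd)
      px <- px + step * cos(theta)
      py <- py + step * sin(theta)
      # reflect at the circular wall and turn the heading inward
      d <- sqrt((px - ctr[1])^2 + (py - ctr[2])^2)
      out <- which(d > R)
      if (length(out)) {
        fac <- (2 * R - d[out]) / d[out]
        px[out] <- ctr[1] + (px[out] - ctr[1]) * fac
        py[out] <- ctr[2] + (py[out] - ctr[2]) * fac
        # reflect the velocity about the wall tangent
        phi <- atan2(py[out] - ctr[2], px[out] - ctr[1])
        theta[out] <- 2 * phi + pi - theta[out]
      }
      x[t, ] <- px; y[t, ] <- py
    }
    trajectory_set(x, y, p$frame_rate_hz, p$arena, source_id = "zonal-shoal")
  })
}

#' Social-preference single-fish generator
#'
#' A biased random walk emulating a test fish in the rectangular preference
#' chamber: per frame, an isotropic Gaussian step plus a constant drift of
#' `bias_mm_s / frame_rate_hz` toward the stimulus-side wall, with reflecting
#' boundaries at the test-area walls. `bias_mm_s = 0` gives a symmetric walk
#' (expected time in the social half = 50%).
#'
#' @param geometry a [rectangular_chamber()] with `stimulus_side` set.
#' @param bias_mm_s drift speed toward the stimulus wall, mm/s (>= 0 drifts
#'   toward it; negative values drift away and are allowed for controls).
#' @param step_sd_mm per-coordinate SD of the Gaussian step, mm/frame.
#' @param frame_rate_hz frames per second (20 matches the 3-8 wpf assay,
#'   30 the 2 wpf assay).
#' @param duration_s total duration; the default 1320 s covers the 10 min
#'   habituation plus 12 min test protocol.
#' @param seed integer seed.
#' @return A `PreferenceSimParams` object.
#' @export
preference_sim_params <- function(geometry = rectangular_chamber(),
                                  bias_mm_s = 0, step_sd_mm = 0.5,
                                  frame_rate_hz = 20, duration_s = 1320,
                                  seed = NULL) {
  if (!is_rectangular(geometry)) stopf("geometry must be a rectangular chamber")
  if (step_sd_mm <= 0) stopf("step_sd_mm must be positive")
  structure(
    list(
      geometry = geometry, bias_mm_s = bias_mm_s, step_sd_mm = step_sd_mm,
      frame_rate_hz = frame_rate_hz, duration_s = duration_s, seed = seed
    ),
    class = "PreferenceSimParams"
  )
}

# reflect a scalar into [lo, hi] by repeated folding
reflect_into <- function(v, lo, hi) {
  w <- hi - lo
  while (v < lo || v > hi) {
    if (v < lo) v <- 2 * lo - v
    if (v > hi) v <- 2 * hi - v
  }
  v
}

#' @rdname preference_sim_params
#' @param p a `PreferenceSimParams` object.
#' @return `simulate_preference_fish()`: a single-fish
#'   [TrajectorySet][trajectory_set].
#' @export
simulate_preference_fish <- function(p) {
  stopifnot(inherits(p, "PreferenceSimParams"))
  g <- p$geometry
  T <- round(p$duration_s * p$frame_rate_hz)
  if (T < 2) stopf("duration too short")
  W <- g$test_width_mm; L <- g$test_length_mm
  drift <- p$bias_mm_s / p$frame_rate_hz *
    if (g$stimulus_side == "left") -1 else 1
  with_rng_seed(p$seed, {
    sx <- rnorm(T - 1L, drift, p$step_sd_mm)
    sy <- rnorm(T - 1L, 0, p$step_sd_mm)
    x <- numeric(T); y <- numeric(T)
    # fish are introduced at the center of the test area
    x[1] <- W / 2; y[1] <- L / 2
    cx <- x[1]; cy <- y[1]
    for (t in seq_len(T - 1L)) {
      cx <- reflect_into(cx + sx[t], 0, W)
      cy <- reflect_into(cy + sy[t], 0, L)
      x[t + 1L] <- cx; y[t + 1L] <- cy
    }
    trajectory_set(cbind(x), cbind(y), p$frame_rate_hz, g,
                   fish_ids = "testfish", source_id = "preference-sim")
  })
}

#' Add synthetic tracking dropouts
#'
#' Masks random runs of frames per fish as missing, emulating the dropouts a
#' video tracker produces (occlusions, reflections). Gap starts are drawn per
#' frame with probability `rate / mean_length_frames` and gap lengths are
#' geometric with the given mean, so the expected fraction of missing samples
#' is roughly `rate`.
#'
#' @param ts a [TrajectorySet][trajectory_set].
#' @param rate target fraction of samples lost per fish (0-1).
#' @param mean_length_frames mean dropout length, frames.
#' @param seed integer seed.
#' @return A new `TrajectorySet` with missing samples.
#' @export
add_dropouts <- function(ts, rate = 0.02, mean_length_frames = 3, seed = NULL) {
  stopifnot(inherits(ts, "TrajectorySet"))
  if (rate < 0 || rate >= 1) stopf("rate must lie in [0, 1)")
  if (rate == 0) return(ts)
  T <- n_frames(ts)
  x <- ts$x; y <- ts$y
  p_start <- rate / mean_length_frames
  with_rng_seed(seed, {
    for (j in seq_len(n_fish(ts))) {
      starts <- which(runif(T) < p_start)
      for (s in starts) {
        len <- 1L + stats::rgeom(1, 1 / mean_length_frames)
        idx <- s:min(T, s + len - 1L)
        x[idx, j] <- NA_real_
        y[idx, j] <- NA_real_
      }
    }
  })
  trajectory_set(x, y, ts$frame_rate_hz, ts$arena, ts$fish_ids, ts$source_id)
}
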