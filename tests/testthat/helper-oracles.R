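# Independent oracles and fixture builders used across the suite.

# Static trajectory set: every fish sits at its (x, y) for `frames` frames.
static_ts <- function(xs, ys, frames = 2, fps = 30, arena = circular_arena(700)) {
  trajectory_set(
    x = matrix(rep(xs, each = frames), frames, length(xs)),
    y = matrix(rep(ys, each = frames), frames, length(ys)),
    frame_rate_hz = fps, arena = arena
  )
}

# Random smooth-ish trajectory set with optional dropouts, for property tests.
random_ts <- function(n_fish = 4, frames = 50, fps = 30, dropout = 0,
                      arena = circular_arena(700), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ctr <- arena$diameter_mm / 2
  x <- matrix(ctr + cumsum(rnorm(frames * n_fish, 0, 2)), frames, n_fish)
  y <- matrix(ctr + cumsum(rnorm(frames * n_fish, 0, 2)), frames, n_fish)
  ts <- trajectory_set(x, y, fps, arena)
  if (dropout > 0) ts <- add_dropouts(ts, rate = dropout, seed = 1)
  ts
}

# Brute-force two-sided rank-sum p-value: enumerate every way to label
# m of the pooled values as group a, score U, and take the symmetric tail.
brute_rank_sum_p <- function(a, b) {
  vals <- c(a, b)
  m <- length(a); n <- length(b)
  u_of <- function(aa, bb) sum(outer(aa, bb, ">")) + 0.5 * sum(outer(aa, bb, "=="))
  U_obs <- u_of(a, b)
  mu <- m * n / 2
  idx <- utils::combn(m + n, m)
  Us <- apply(idx, 2, function(ii) u_of(vals[ii], vals[-ii]))
  mean(abs(Us - mu) >= abs(U_obs - mu) - 1e-12)
}

# Monte-Carlo permutation p for the Kruskal-Wallis H (label shuffles).
mc_kw_p <- function(groups, n_perm = 20000) {
  values <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  H_obs <- shoalkit:::kw_statistic(values, g)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    if (shoalkit:::kw_statistic(values, sample(g)) >= H_obs - 1e-12) {
      hits <- hits + 1L
    }
  }
  (hits + 1) / (n_perm + 1)
}

# Singular-value route to the variance-explained statistic, independent of
# the covariance-eigendecomposition route in the package.
svd_variance_explained <- function(M, k = 2) {
  Mc <- M - rowMeans(M)
  d2 <- svd(Mc, nu = 0, nv = 0)$d^2
  sum(d2[seq_len(k)]) / sum(d2)
}
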