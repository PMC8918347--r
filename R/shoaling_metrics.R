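#' Neighbor distance statistics of a shoal
#'
#' Per frame and focal fish, the Euclidean distances to all other tracked
#' fish yield the nearest-neighbor distance (minimum), inter-individual
#' distance (mean) and farthest-neighbor distance (maximum). Frames where a
#' focal/neighbor pair is untracked are dropped pairwise. Per-fish values are
#' time averages; the shoal-level value is the mean over fish.
#'
#' For every fish and frame `nnd <= iid <= fnd` holds by construction.
#'
#' @param ts a [TrajectorySet][trajectory_set] with at least 2 fish.
#' @param keep_frames also return the per-frame, per-fish distance matrices
#'   (T x N), for diagnostics.
#' @return A list with `per_fish` (data frame: `fish_id`, `nnd_mm`, `iid_mm`,
#'   `fnd_mm`), `shoal` (named vector `nnd_mm`, `iid_mm`, `fnd_mm`, plus
#'   `iid_pair_mm`, the mean over unordered pairs), and, if requested,
#'   `frames` (list of T x N matrices `nnd`, `iid`, `fnd`).
#' @examples
#' # three fish in a 3-4-5 configuration, static
#' a <- circular_arena(700)
#' ts <- trajectory_set(x = rbind(c(0, 3, 6), c(0, 3, 6)),
#'                      y = rbind(c(0, 4, 8), c(0, 4, 8)),
#'                      frame_rate_hz = 30, arena = a)
#' neighbor_distances(ts)$shoal  # nnd 5, iid 6.67, fnd 8.33
#' @export
neighbor_distances <- function(ts, keep_frames = FALSE) {
  stopifnot(inherits(ts, "TrajectorySet"))
  N <- n_fish(ts)
  if (N < 2L) stopf("neighbor distances need at least 2 fish")
  T <- n_frames(ts)
  pairs <- utils::combn(N, 2)
  P <- ncol(pairs)
  D <- matrix(NA_real_, T, P)
  for (p in seq_len(P)) {
    i <- pairs[1, p]; j <- pairs[2, p]
    D[, p] <- sqrt((ts$x[, i] - ts$x[, j])^2 + (ts$y[, i] - ts$y[, j])^2)
  }
  nnd_t <- matrix(NA_real_, T, N)
  iid_t <- matrix(NA_real_, T, N)
  fnd_t <- matrix(NA_real_, T, N)
  for (i in seq_len(N)) {
    cols <- which(pairs[1, ] == i | pairs[2, ] == i)
    sub <- D[, cols, drop = FALSE]
    args <- c(lapply(seq_len(ncol(sub)), function(k) sub[, k]), list(na.rm = TRUE))
    nnd_t[, i] <- do.call(pmin, args)
    fnd_t[, i] <- do.call(pmax, args)
    m <- rowMeans(sub, na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    iid_t[, i] <- m
  }
  per_fish <- data.frame(
    fish_id = ts$fish_ids,
    nnd_mm = colMeans(nnd_t, na.rm = TRUE),
    iid_mm = colMeans(iid_t, na.rm = TRUE),
    fnd_mm = colMeans(fnd_t, na.rm = TRUE),
    row.names = NULL
  )
  for (col in c("nnd_mm", "iid_mm", "fnd_mm")) {
    per_fish[[col]][is.nan(per_fish[[col]])] <- NA_real_
  }
  if (anyNA(per_fish$nnd_mm)) {
    warning("some fish were never co-tracked with another fish; ",
            "their neighbor distances are NA", call. = FALSE)
  }
  shoal <- c(
    nnd_mm = mean(per_fish$nnd_mm, na.rm = TRUE),
    iid_mm = mean(per_fish$iid_mm, na.rm = TRUE),
    fnd_mm = mean(per_fish$fnd_mm, na.rm = TRUE),
    iid_pair_mm = mean(D, na.rm = TRUE)
  )
  out <- list(per_fish = per_fish, shoal = shoal)
  if (keep_frames) out$frames <- list(nnd = nnd_t, iid = iid_t, fnd = fnd_t)
  out
}

#' Cumulative shoal distance
#'
#' The shoal's total swimming activity: by default the sum over fish of
#' per-fish path lengths (the sum of consecutive-frame step lengths over
#' tracked pairs). A centroid-path-length alternative is available via
#' `method = "centroid"`.
#'
#' @param ts a [TrajectorySet][trajectory_set].
#' @param method `"per_fish"` (default; sum of per-fish path lengths) or
#'   `"centroid"` (path length of the shoal centroid).
#' @return Distance in mm.
#' @export
cumulative_shoal_distance <- function(ts, method = c("per_fish", "centroid")) {
  stopifnot(inherits(ts, "TrajectorySet"))
  method <- match.arg(method)
  if (method == "per_fish") {
    total <- 0
    for (j in seq_len(n_fish(ts))) {
      x <- ts$x[, j]; y <- ts$y[, j]
      ok <- !is.na(x)
      pair_ok <- ok[-length(ok)] & ok[-1L]
      if (any(pair_ok)) {
        total <- total + sum(sqrt(diff(x)^2 + diff(y)^2)[pair_ok])
      }
    }
    total
  } else {
    cx <- rowMeans(ts$x, na.rm = TRUE)
    cy <- rowMeans(ts$y, na.rm = TRUE)
    ok <- is.finite(cx)
    pair_ok <- ok[-length(ok)] & ok[-1L]
    if (!any(pair_ok)) return(0)
    sum(sqrt(diff(cx)^2 + diff(cy)^2)[pair_ok])
  }
}

#' Assemble the 2N x T trajectory matrix
#'
#' Stacks the x- and y-components of all individual trajectories into a
#' matrix with 2N rows (fish-major: `fish1_x, fish1_y, fish2_x, ...`) and
#' one column per retained frame. Frames containing any missing sample are
#' dropped (listwise), and the retained-frame mask is recorded. A gap-free
#' 20-fish, 30-min, 30-fps recording yields the canonical 40 x 54,000
#' matrix.
#'
#' @param ts a [TrajectorySet][trajectory_set].
#' @return A `TrajectoryMatrix`: list with `matrix` (2N x T_retained, row
#'   names `<fish>_x` / `<fish>_y`), `frames_retained` (logical, length T)
#'   and `n_fish`.
#' @export
assemble_trajectory_matrix <- function(ts) {
  stopifnot(inherits(ts, "TrajectorySet"))
  complete <- rowSums(is.na(ts$x)) == 0L
  if (!any(complete)) {
    stopf("no frame has all %d fish tracked; trajectory matrix is empty",
          n_fish(ts))
  }
  xs <- t(ts$x[complete, , drop = FALSE])
  ys <- t(ts$y[complete, , drop = FALSE])
  N <- n_fish(ts)
  M <- matrix(NA_real_, 2L * N, ncol(xs))
  M[seq(1, 2 * N, by = 2), ] <- xs
  M[seq(2, 2 * N, by = 2), ] <- ys
  rownames(M) <- as.vector(rbind(paste0(ts$fish_ids, "_x"),
                                 paste0(ts$fish_ids, "_y")))
  structure(
    list(matrix = M, frames_retained = complete, n_fish = N),
    class = "TrajectoryMatrix"
  )
}

#' @export
print.TrajectoryMatrix <- function(x, ...) {
  cat(sprintf("<TrajectoryMatrix> %d x %d (%d of %d frames retained)\n",
              nrow(x$matrix), ncol(x$matrix),
              sum(x$frames_retained), length(x$frames_retained)))
  invisible(x)
}

#' Variance explained by the leading principal components
#'
#' Centers each row of the trajectory matrix by its time mean, eigen
#' decomposes the 2N x 2N sample covariance across time (unbiased, T-1
#' denominator; covariance, not correlation — no variance scaling), and
#' returns the fraction of total variance carried by the top `k`
#' eigenvalues. With `k = 2` this is the shoal polarization statistic: for
#' coordinated shoals the first two components capture the x/y motion of
#' the shoal centroid, so the statistic approaches 1; for independent fish
#' it approaches `1/N`.
#'
#' @param m a [TrajectoryMatrix][assemble_trajectory_matrix] or a plain
#'   numeric matrix of 2N rows x T columns.
#' @param k number of leading components (default 2).
#' @param keep_components also return the eigenvectors.
#' @return A `PCAResult`: list with `eigenvalues` (sorted, length 2N),
#'   `variance_explained` (top-k fraction), `k`, `n_fish`, and optionally
#'   `components`.
#' @export
variance_explained <- function(m, k = 2L, keep_components = FALSE) {
  M <- if (inherits(m, "TrajectoryMatrix")) m$matrix else as.matrix(m)
  if (ncol(M) < 2L) stopf("need at least 2 frames for a covariance")
  k <- as.integer(k)
  if (k < 1L || k > nrow(M)) stopf("k must lie in [1, %d]", nrow(M))
  Mc <- M - rowMeans(M)
  C <- tcrossprod(Mc) / (ncol(M) - 1)
  ev <- eigen(C, symmetric = TRUE, only.values = !keep_components)
  lambda <- pmax(ev$values, 0)  # clip numerical negatives
  total <- sum(lambda)
  if (total <= .Machine$double.eps * nrow(M)) {
    stopf("total variance is zero (all fish stationary); statistic undefined")
  }
  out <- list(
    eigenvalues = lambda,
    variance_explained = sum(lambda[seq_len(k)]) / total,
    k = k,
    n_fish = nrow(M) / 2
  )
  if (keep_components) out$components <- ev$vectors
  structure(out, class = "PCAResult")
}

#' @export
print.PCAResult <- function(x, ...) {
  cat(sprintf("<PCAResult> variance explained by top %d PCs: %.4f (2N = %d)\n",
              x$k, x$variance_explained, length(x$eigenvalues)))
  invisible(x)
}

#' Mixed-movie randomization control
#'
#' Composes pseudo-shoals of `k_same` fish drawn from one recording plus
#' `n_total - k_same` fish drawn one each from distinct other recordings,
#' and computes the variance-explained statistic of each composition. Fish
#' from different recordings cannot be coordinated, so the statistic should
#' be near `1/n_total` at `k_same = 0` and increase continuously toward the
#' true-shoal value as `k_same` grows.
#'
#' @param recordings list of [TrajectorySet][trajectory_set]s (the "movies");
#'   all are truncated to the shortest frame count.
#' @param k_same integer vector of same-movie fish counts to evaluate.
#' @param n_total pseudo-shoal size (default 20).
#' @param replicates random compositions per `k_same` value.
#' @param seed integer seed.
#' @return Data frame with one row per `k_same`: `k_same`, `mean_ve`,
#'   `sd_ve`, `replicates`.
#' @export
mixed_shoal_control <- function(recordings, k_same = 0:20, n_total = 20L,
                                replicates = 10L, seed = NULL) {
  if (!is.list(recordings) || length(recordings) < 2L) {
    stopf("need a list of at least 2 recordings")
  }
  lapply(recordings, function(r) stopifnot(inherits(r, "TrajectorySet")))
  n_total <- as.integer(n_total)
  k_same <- as.integer(k_same)
  if (any(k_same < 0L | k_same > n_total)) {
    stopf("k_same values must lie in [0, n_total]")
  }
  Tmin <- min(vapply(recordings, n_frames, integer(1)))
  if (Tmin < 2L) stopf("recordings too short")
  R <- length(recordings)
  for (k in k_same) {
    need <- if (k > 0L) 1L + (n_total - k) else n_total
    if (R < need) {
      stopf("k_same = %d needs %d distinct recordings, have %d", k, need, R)
    }
  }
  fr <- recordings[[1]]$frame_rate_hz
  with_rng_seed(seed, {
    res <- lapply(k_same, function(k) {
      ves <- vapply(seq_len(replicates), function(rep) {
        x <- matrix(NA_real_, Tmin, n_total)
        y <- matrix(NA_real_, Tmin, n_total)
        col <- 0L
        if (k > 0L) {
          focal <- sample.int(R, 1L)
          nf <- n_fish(recordings[[focal]])
          if (nf < k) stopf("focal recording has only %d fish, need %d", nf, k)
          fsel <- sample.int(nf, k)
          for (f in fsel) {
            col <- col + 1L
            x[, col] <- recordings[[focal]]$x[seq_len(Tmin), f]
            y[, col] <- recordings[[focal]]$y[seq_len(Tmin), f]
          }
          others <- setdiff(seq_len(R), focal)
        } else {
          others <- seq_len(R)
        }
        if (n_total - k > 0L) {
          osel <- sample(others, n_total - k)
          for (o in osel) {
            col <- col + 1L
            f <- sample.int(n_fish(recordings[[o]]), 1L)
            x[, col] <- recordings[[o]]$x[seq_len(Tmin), f]
            y[, col] <- recordings[[o]]$y[seq_len(Tmin), f]
          }
        }
        pseudo <- trajectory_set(x, y, fr, recordings[[1]]$arena,
                                 source_id = sprintf("mixed-k%d", k))
        m <- assemble_trajectory_matrix(pseudo)
        variance_explained(m)$variance_explained
      }, numeric(1))
      data.frame(k_same = k, mean_ve = mean(ves), sd_ve = sd(ves),
                 replicates = replicates)
    })
    do.call(rbind, res)
  })
}

#' All shoal metrics for one recording
#'
#' Aggregates the neighbor distances, cumulative shoal distance and
#' variance-explained polarization statistic into one record per shoal.
#'
#' @param ts a [TrajectorySet][trajectory_set] with >= 2 fish.
#' @return One-row data frame: `source_id`, `n_fish`, `frames_used`,
#'   `nnd_mm`, `iid_mm`, `fnd_mm`, `cumulative_distance_mm`,
#'   `variance_explained_2`.
#' @export
shoal_metrics <- function(ts) {
  stopifnot(inherits(ts, "TrajectorySet"))
  nd <- neighbor_distances(ts)
  m <- assemble_trajectory_matrix(ts)
  ve <- variance_explained(m, k = 2L)
  data.frame(
    source_id = ts$source_id,
    n_fish = n_fish(ts),
    frames_used = sum(m$frames_retained),
    nnd_mm = unname(nd$shoal["nnd_mm"]),
    iid_mm = unname(nd$shoal["iid_mm"]),
    fnd_mm = unname(nd$shoal["fnd_mm"]),
    cumulative_distance_mm = cumulative_shoal_distance(ts),
    variance_explained_2 = ve$variance_explained,
    row.names = NULL
  )
}
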