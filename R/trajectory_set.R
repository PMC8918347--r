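#' Trajectory sets
#'
#' A `TrajectorySet` holds the 2-D positions of N fish over T frames at a
#' fixed frame rate, in mm, with tracking dropouts marked as missing samples
#' (`NA` in both coordinates). It is the common currency of all assay
#' analyses.
#'
#' @param x,y numeric T x N matrices of positions in mm (one column per fish,
#'   one row per frame); `NA` marks a missing sample. If either coordinate of
#'   a sample is `NA` the whole sample is treated as missing.
#' @param frame_rate_hz frames per second, > 0 (recordings here use 20 or
#'   30 fps, but any positive rate is accepted).
#' @param arena an [ArenaGeometry][rectangular_chamber] the positions refer to.
#' @param fish_ids optional character vector of fish identifiers (defaults to
#'   `fish01`, `fish02`, ...).
#' @param source_id recording/movie identifier carried through to outputs.
#' @return An object of class `TrajectorySet`.
#' @seealso [read_trajectories()], [fill_gaps()], [mean_swim_speed()]
#' @export
trajectory_set <- function(x, y, frame_rate_hz, arena,
                           fish_ids = NULL, source_id = "unknown") {
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (!all(dim(x) == dim(y))) stopf("x and y matrices must have the same shape")
  if (nrow(x) < 1L) stopf("a TrajectorySet needs at least one frame")
  if (ncol(x) < 1L) stopf("a TrajectorySet needs at least one fish")
  if (!is.numeric(frame_rate_hz) || length(frame_rate_hz) != 1L ||
      !is.finite(frame_rate_hz) || frame_rate_hz <= 0) {
    stopf("frame_rate_hz must be a single positive number")
  }
  if (!inherits(arena, "ArenaGeometry")) stopf("arena must be an ArenaGeometry")
  n <- ncol(x)
  if (is.null(fish_ids)) fish_ids <- sprintf("fish%02d", seq_len(n))
  fish_ids <- as.character(fish_ids)
  if (length(fish_ids) != n) stopf("fish_ids length must equal the number of fish")
  if (anyDuplicated(fish_ids)) stopf("fish_ids must be unique")
  # a sample is missing if either coordinate is
  miss <- is.na(x) | is.na(y)
  x[miss] <- NA_real_
  y[miss] <- NA_real_
  dimnames(x) <- dimnames(y) <- list(NULL, fish_ids)
  structure(
    list(
      fish_ids = fish_ids,
      x = x, y = y,
      frame_rate_hz = frame_rate_hz,
      arena = arena,
      source_id = as.character(source_id)
    ),
    class = "TrajectorySet"
  )
}

#' @rdname trajectory_set
#' @param ts a `TrajectorySet`.
#' @export
n_fish <- function(ts) {
  stopifnot(inherits(ts, "TrajectorySet"))
  ncol(ts$x)
}

#' @rdname trajectory_set
#' @export
n_frames <- function(ts) {
  stopifnot(inherits(ts, "TrajectorySet"))
  nrow(ts$x)
}

#' @export
print.TrajectorySet <- function(x, ...) {
  cat(sprintf(
    "<TrajectorySet> %d fish x %d frames @ %g fps (%.1f s), source '%s'\n",
    n_fish(x), n_frames(x), x$frame_rate_hz,
    n_frames(x) / x$frame_rate_hz, x$source_id
  ))
  miss <- sum(is.na(x$x))
  cat(sprintf("  missing samples: %d (%.2f%%)\n", miss,
              100 * miss / length(x$x)))
  print(x$arena)
  invisible(x)
}

# TRUE for samples present (tracked) in fish column `j`
present_mask <- function(ts) !is.na(ts$x)

# Resolve a half-open frame window [start, end) given in 0-based frame
# indices into 1-based row indices. window = NULL means all frames.
resolve_window <- function(ts, window) {
  T <- n_frames(ts)
  if (is.null(window)) return(seq_len(T))
  if (length(window) != 2L || !is.numeric(window)) {
    stopf("window must be c(start, end), 0-based and half-open")
  }
  start <- as.integer(window[1]); end <- as.integer(window[2])
  if (start < 0L || end > T || start >= end) {
    stopf("window [%d, %d) is empty or outside the recording (T = %d)",
          start, end, T)
  }
  seq.int(start + 1L, end)
}

resolve_fish <- function(ts, fish) {
  if (is.character(fish)) {
    j <- match(fish, ts$fish_ids)
    if (is.na(j)) stopf("no fish with id '%s'", fish)
    j
  } else {
    j <- as.integer(fish)
    if (j < 1L || j > n_fish(ts)) stopf("fish index %d out of range", j)
    j
  }
}

#' Interpolate short tracking gaps
#'
#' Gaps (runs of missing samples) of length at most `max_gap_frames` that are
#' flanked by tracked samples are filled by per-coordinate linear
#' interpolation; longer gaps and gaps at the start or end of the recording
#' are left missing. Originally present samples are never modified.
#'
#' @param ts a [TrajectorySet][trajectory_set].
#' @param max_gap_frames maximum gap length (frames) to interpolate;
#'   default 5 frames (~0.17 s at 30 fps). `0` disables filling.
#' @return A new `TrajectorySet`; the input is not modified.
#' @export
fill_gaps <- function(ts, max_gap_frames = 5L) {
  stopifnot(inherits(ts, "TrajectorySet"))
  max_gap_frames <- as.integer(max_gap_frames)
  if (is.na(max_gap_frames) || max_gap_frames < 0L) {
    stopf("max_gap_frames must be a non-negative integer")
  }
  if (max_gap_frames == 0L) return(ts)
  x <- ts$x; y <- ts$y
  T <- nrow(x)
  for (j in seq_len(ncol(x))) {
    missing <- is.na(x[, j])
    if (!any(missing) || all(missing)) next
    r <- rle(missing)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      len <- r$lengths[k]
      if (len > max_gap_frames) next
      s <- starts[k]; e <- ends[k]
      if (s == 1L || e == T) next  # leading/trailing gap
      idx <- s:e
      w <- (idx - (s - 1L)) / (len + 1L)
      x[idx, j] <- x[s - 1L, j] + w * (x[e + 1L, j] - x[s - 1L, j])
      y[idx, j] <- y[s - 1L, j] + w * (y[e + 1L, j] - y[s - 1L, j])
    }
  }
  trajectory_set(x, y, ts$frame_rate_hz, ts$arena, ts$fish_ids, ts$source_id)
}

#' Mean swimming speed of one fish
#'
#' The average speed over a frame window, computed from consecutive-frame
#' displacements only (no smoothing): the mean Euclidean step length over
#' consecutive pairs of tracked frames, times the frame rate. Pairs spanning
#' a tracking gap contribute to neither numerator nor denominator.
#'
#' @param ts a [TrajectorySet][trajectory_set].
#' @param fish fish identifier or column index.
#' @param window half-open frame interval `c(start, end)` in 0-based frames,
#'   or `NULL` for the whole recording.
#' @return Mean speed in mm/s.
#' @examples
#' arena <- rectangular_chamber()
#' ts <- trajectory_set(x = cbind(c(10, 10, 13)), y = cbind(c(10, 10, 14)),
#'                      frame_rate_hz = 20, arena = arena)
#' mean_swim_speed(ts, 1)  # steps of 0 and 5 mm at 20 fps -> 50 mm/s
#' @export
mean_swim_speed <- function(ts, fish, window = NULL) {
  stopifnot(inherits(ts, "TrajectorySet"))
  j <- resolve_fish(ts, fish)
  rows <- resolve_window(ts, window)
  x <- ts$x[rows, j]; y <- ts$y[rows, j]
  ok <- !is.na(x)
  if (sum(ok) < 2L) {
    stopf("speed undefined: fewer than 2 tracked frames in the window")
  }
  pair_ok <- ok[-length(ok)] & ok[-1L]
  if (!any(pair_ok)) {
    stopf("speed undefined: no consecutive pair of tracked frames in the window")
  }
  steps <- sqrt(diff(x)^2 + diff(y)^2)[pair_ok]
  mean(steps) * ts$frame_rate_hz
}

#' Per-fish mean speeds over a window
#'
#' Vectorized convenience over [mean_swim_speed()]; fish whose speed is
#' undefined in the window get `NA`.
#'
#' @inheritParams mean_swim_speed
#' @return Named numeric vector (mm/s), one entry per fish.
#' @export
swim_speeds <- function(ts, window = NULL) {
  stopifnot(inherits(ts, "TrajectorySet"))
  out <- vapply(seq_len(n_fish(ts)), function(j) {
    tryCatch(mean_swim_speed(ts, j, window), error = function(e) NA_real_)
  }, numeric(1))
  names(out) <- ts$fish_ids
  out
}

# Subset frames (1-based row indices), keeping metadata.
subset_frames <- function(ts, rows) {
  trajectory_set(ts$x[rows, , drop = FALSE], ts$y[rows, , drop = FALSE],
                 ts$frame_rate_hz, ts$arena, ts$fish_ids, ts$source_id)
}

# Subset fish (indices or ids), keeping metadata.
subset_fish <- function(ts, fish) {
  j <- vapply(fish, function(f) resolve_fish(ts, f), integer(1))
  trajectory_set(ts$x[, j, drop = FALSE], ts$y[, j, drop = FALSE],
                 ts$frame_rate_hz, ts$arena, ts$fish_ids[j], ts$source_id)
}
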