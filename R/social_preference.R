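#' Social and antisocial regions of interest
#'
#' Splits the rectangular test area into two ROIs at the midline
#' perpendicular to its long axis: the half adjacent to the occupied
#' stimulus area is the "social ROI", the opposite half the "antisocial
#' ROI". Together the ROIs partition the test area.
#'
#' Boundary tie rule (deterministic, measure-zero on continuous data): a
#' point exactly on the midline counts as social; points on the outer walls
#' count as inside the test area. The antisocial ROI is therefore half-open
#' at the midline.
#'
#' @param geometry a [rectangular_chamber()] with `stimulus_side` set.
#' @return A list with elements `social` and `antisocial`, each a
#'   `RegionOfInterest`.
#' @examples
#' rois <- build_rois(rectangular_chamber(25, 75, stimulus_side = "left"))
#' rois$social  # left 12.5 x 75 mm half
#' @export
build_rois <- function(geometry) {
  if (!is_rectangular(geometry)) {
    stopf("ROIs are defined for the rectangular preference chamber only")
  }
  if (is.null(geometry$stimulus_side)) {
    stopf("geometry must specify which stimulus area is occupied (stimulus_side)")
  }
  W <- geometry$test_width_mm
  L <- geometry$test_length_mm
  mk <- function(label, xmin, xmax, xmin_closed, xmax_closed) {
    structure(
      list(label = label, xmin = xmin, xmax = xmax,
           ymin = 0, ymax = L,
           xmin_closed = xmin_closed, xmax_closed = xmax_closed),
      class = "RegionOfInterest"
    )
  }
  if (geometry$stimulus_side == "left") {
    list(
      social = mk("social", 0, W / 2, TRUE, TRUE),
      antisocial = mk("antisocial", W / 2, W, FALSE, TRUE)
    )
  } else {
    list(
      social = mk("social", W / 2, W, TRUE, TRUE),
      antisocial = mk("antisocial", 0, W / 2, TRUE, FALSE)
    )
  }
}

#' @export
print.RegionOfInterest <- function(x, ...) {
  cat(sprintf("<RegionOfInterest> %s: x %s%g, %g%s, y [%g, %g] mm\n",
              x$label,
              if (x$xmin_closed) "[" else "(", x$xmin,
              x$xmax, if (x$xmax_closed) "]" else ")",
              x$ymin, x$ymax))
  invisible(x)
}

roi_contains <- function(roi, x, y) {
  in_x <- (if (roi$xmin_closed) x >= roi$xmin else x > roi$xmin) &
    (if (roi$xmax_closed) x <= roi$xmax else x < roi$xmax)
  in_x & y >= roi$ymin & y <= roi$ymax
}

#' Percentage of time spent inside an ROI
#'
#' The percentage of tracked (non-missing) frames in the window whose
#' position falls inside the ROI. Frames lost to tracking dropouts are
#' excluded from both numerator and denominator.
#'
#' @param ts a single-fish [TrajectorySet][trajectory_set].
#' @param roi a `RegionOfInterest` from [build_rois()].
#' @param window half-open 0-based frame interval `c(start, end)`, or `NULL`
#'   for all frames.
#' @return Percentage in `[0, 100]`.
#' @export
fraction_time_in_roi <- function(ts, roi, window = NULL) {
  stopifnot(inherits(ts, "TrajectorySet"), inherits(roi, "RegionOfInterest"))
  if (n_fish(ts) != 1L) {
    stopf("ROI scoring expects a single-fish TrajectorySet (got %d fish)",
          n_fish(ts))
  }
  rows <- resolve_window(ts, window)
  x <- ts$x[rows, 1]; y <- ts$y[rows, 1]
  ok <- !is.na(x)
  if (!any(ok)) stopf("all frames in the window are missing; ROI time undefined")
  100 * sum(roi_contains(roi, x[ok], y[ok])) / sum(ok)
}

#' Speed-based exclusion threshold
#'
#' Fish with reduced motion (e.g. freezing) are excluded using a threshold
#' computed per age group: the mean swimming speed of each genotype group,
#' times 0.6 for the smallest group mean.
#'
#' @param group_mean_speeds numeric vector of per-genotype-group mean speeds
#'   (mm/s), all >= 0.
#' @return Threshold in mm/s: `0.6 * min(group_mean_speeds)`.
#' @examples
#' exclusion_threshold(c(10, 8, 12))  # 4.8
#' @export
exclusion_threshold <- function(group_mean_speeds) {
  v <- as.numeric(group_mean_speeds)
  if (length(v) < 1L) stopf("need at least one group mean speed")
  if (any(!is.finite(v)) || any(v < 0)) {
    stopf("group mean speeds must be finite and >= 0")
  }
  0.6 * min(v)
}

#' Assay protocol timing
#'
#' The preference assay consists of a 10-min habituation (no stimulus fish)
#' followed by a 12-min test phase; scoring uses the last 10 min of the test,
#' because freshly transferred stimulus fish need up to 2 min to behave
#' normally.
#'
#' @param habituation_s habituation duration, seconds.
#' @param test_s test-phase duration, seconds.
#' @param analysis_last_s length of the analysis window at the end of the
#'   test phase, seconds.
#' @return An `AssayProtocol` object.
#' @export
assay_protocol <- function(habituation_s = 600, test_s = 720,
                           analysis_last_s = 600) {
  if (habituation_s < 0 || test_s <= 0) stopf("phase durations must be positive")
  if (analysis_last_s <= 0 || analysis_last_s > test_s) {
    stopf("the analysis window must be a non-empty suffix of the test phase")
  }
  structure(
    list(habituation_s = habituation_s, test_s = test_s,
         analysis_last_s = analysis_last_s),
    class = "AssayProtocol"
  )
}

protocol_windows <- function(protocol, frame_rate_hz) {
  hab_end <- round(protocol$habituation_s * frame_rate_hz)
  test_end <- round((protocol$habituation_s + protocol$test_s) * frame_rate_hz)
  ana_start <- test_end - round(protocol$analysis_last_s * frame_rate_hz)
  list(
    habituation = c(0, hab_end),
    test = c(hab_end, test_end),
    analysis = c(ana_start, test_end)
  )
}

#' Score one social-preference assay
#'
#' Computes the percentage of time in the social ROI over the analysis
#' window, the mean swim speed in both phases, and the inclusion flag:
#' `included` is `TRUE` iff the exclusion-basis speed is greater than or
#' equal to `threshold_mm_s` (a fish exactly at the threshold is included).
#'
#' @param ts a single-fish [TrajectorySet][trajectory_set] covering
#'   habituation plus test.
#' @param protocol an [assay_protocol()].
#' @param geometry chamber geometry; defaults to the trajectory's arena.
#' @param threshold_mm_s exclusion threshold from [exclusion_threshold()].
#' @param exclusion_basis which phase's speed gates exclusion: the test
#'   phase (default), habituation, or the minimum of both.
#' @return A `PreferenceResult`: list with `percent_time_social`,
#'   `mean_speed_test`, `mean_speed_habituation`, `included`,
#'   `threshold_applied`, and the analysis `window` (0-based frames).
#' @export
score_assay <- function(ts, protocol = assay_protocol(),
                        geometry = ts$arena, threshold_mm_s = 0,
                        exclusion_basis = c("test", "habituation", "min")) {
  stopifnot(inherits(ts, "TrajectorySet"), inherits(protocol, "AssayProtocol"))
  exclusion_basis <- match.arg(exclusion_basis)
  win <- protocol_windows(protocol, ts$frame_rate_hz)
  if (n_frames(ts) < win$test[2]) {
    stopf("trajectory too short for the protocol: need %d frames, have %d",
          win$test[2], n_frames(ts))
  }
  rois <- build_rois(geometry)
  pct <- fraction_time_in_roi(ts, rois$social, win$analysis)
  sp_hab <- mean_swim_speed(ts, 1, win$habituation)
  sp_test <- mean_swim_speed(ts, 1, win$test)
  basis <- switch(exclusion_basis,
                  test = sp_test,
                  habituation = sp_hab,
                  min = min(sp_hab, sp_test))
  structure(
    list(
      percent_time_social = pct,
      mean_speed_test = sp_test,
      mean_speed_habituation = sp_hab,
      included = basis >= threshold_mm_s,
      threshold_applied = threshold_mm_s,
      exclusion_basis = exclusion_basis,
      window = win$analysis
    ),
    class = "PreferenceResult"
  )
}

#' @export
print.PreferenceResult <- function(x, ...) {
  cat(sprintf(
    paste0("<PreferenceResult> %.1f%% time in social ROI; speed %.1f mm/s ",
           "(test), %.1f mm/s (habituation); %s (threshold %.2f mm/s on %s)\n"),
    x$percent_time_social, x$mean_speed_test, x$mean_speed_habituation,
    if (x$included) "included" else "EXCLUDED",
    x$threshold_applied, x$exclusion_basis
  ))
  invisible(x)
}
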