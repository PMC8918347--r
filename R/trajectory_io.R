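#' Read and write trajectory files
#'
#' Trajectories are exchanged as plain CSV in the dialect produced by
#' post-processing multi-animal tracker exports: header
#' `frame,fish_id,x_mm,y_mm`, one row per fish per frame, frames numbered
#' from 0, empty `x_mm`/`y_mm` fields encoding missing samples. A JSON
#' metadata sidecar (same path with a `.json` extension) carries
#' `frame_rate_hz`, the arena geometry, `source_id`, the fish order and an
#' optional `px_per_mm` scale factor applied at ingest (positions are stored
#' internally in mm).
#'
#' Positions are serialized with 6 decimal places (sub-micrometre), so a
#' write/read round trip reproduces the set to that precision.
#'
#' @param path CSV file path.
#' @param geometry optional [ArenaGeometry][rectangular_chamber] overriding
#'   the sidecar's arena.
#' @return `read_trajectories()`: a [TrajectorySet][trajectory_set];
#'   `write_trajectories()`: `path`, invisibly.
#' @export
read_trajectories <- function(path, geometry = NULL) {
  if (!file.exists(path)) stopf("trajectory file '%s' does not exist", path)
  sidecar <- sidecar_path(path)
  if (!file.exists(sidecar)) {
    stopf("missing metadata sidecar '%s' (frame rate/arena/source required)",
          sidecar)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$frame_rate_hz)) {
    stopf("sidecar '%s' lacks frame_rate_hz", sidecar)
  }
  arena <- geometry %||% arena_from_list(meta$arena)
  raw <- read.csv(path, colClasses = c("integer", "character",
                                       "character", "character"))
  required <- c("frame", "fish_id", "x_mm", "y_mm")
  if (!identical(names(raw), required)) {
    stopf("'%s': expected header %s", path, paste(required, collapse = ","))
  }
  parse_coord <- function(v, what) {
    out <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(out) & nzchar(trimws(v)))
    if (length(bad)) {
      stopf("'%s' line %d: malformed %s value '%s'",
            path, bad[1] + 1L, what, v[bad[1]])  # +1 for the header line
    }
    out[!nzchar(trimws(v))] <- NA_real_
    out
  }
  xv <- parse_coord(raw$x_mm, "x_mm")
  yv <- parse_coord(raw$y_mm, "y_mm")
  scale <- meta$px_per_mm
  if (!is.null(scale)) {
    if (!is.numeric(scale) || scale <= 0) stopf("px_per_mm must be positive")
    xv <- xv / scale
    yv <- yv / scale
  }
  ids <- meta$fish_ids %||% unique(raw$fish_id)
  counts <- table(raw$fish_id)
  if (!setequal(names(counts), ids)) {
    stopf("'%s': fish ids in file do not match sidecar fish_ids", path)
  }
  if (length(unique(as.integer(counts))) != 1L) {
    cn <- as.integer(counts)
    stopf("'%s': inconsistent frame counts per fish (%s)", path,
          paste(sprintf("%s=%d", names(counts), cn), collapse = ", "))
  }
  T <- as.integer(counts[[1]])
  frames_expected <- 0:(T - 1L)
  x <- matrix(NA_real_, T, length(ids))
  y <- matrix(NA_real_, T, length(ids))
  for (j in seq_along(ids)) {
    sel <- raw$fish_id == ids[j]
    fr <- raw$frame[sel]
    o <- order(fr)
    if (!identical(as.integer(fr[o]), frames_expected)) {
      stopf("'%s': fish '%s' does not cover frames 0..%d exactly once",
            path, ids[j], T - 1L)
    }
    x[, j] <- xv[sel][o]
    y[, j] <- yv[sel][o]
  }
  trajectory_set(x, y, meta$frame_rate_hz, arena,
                 fish_ids = ids, source_id = meta$source_id %||% basename(path))
}

#' @rdname read_trajectories
#' @param ts a [TrajectorySet][trajectory_set] to write.
#' @export
write_trajectories <- function(ts, path) {
  stopifnot(inherits(ts, "TrajectorySet"))
  if (n_fish(ts) < 1L) stopf("refusing to write an empty TrajectorySet")
  T <- n_frames(ts); N <- n_fish(ts)
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.6f", v))
  df <- data.frame(
    frame = rep(0:(T - 1L), times = N),
    fish_id = rep(ts$fish_ids, each = T),
    x_mm = fmt(as.vector(ts$x)),
    y_mm = fmt(as.vector(ts$y)),
    stringsAsFactors = FALSE
  )
  ok <- tryCatch({
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stopf("could not write trajectory file '%s'", path)
  meta <- list(
    frame_rate_hz = ts$frame_rate_hz,
    arena = arena_to_list(ts$arena),
    source_id = ts$source_id,
    fish_ids = ts$fish_ids
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}
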