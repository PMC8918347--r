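#' Batch run configuration
#'
#' Bundles everything a manifest-driven batch run needs: the manifest (one
#' row per trajectory file with its group labels), protocol/geometry
#' parameters, the gap policy, the statistics design and a seed. Every
#' output table and log line echoes the seed so runs are reproducible.
#'
#' The manifest is a CSV (or data frame) with columns `path`, `fish_id` (or
#' `shoal_id`), `genotype`, `age_wpf`, `rearing`.
#'
#' @param assay `"preference"` or `"shoaling"`.
#' @param manifest path to a manifest CSV, or a data frame.
#' @param out_dir output directory (created if missing).
#' @param protocol an [assay_protocol()] (preference runs).
#' @param geometry optional [ArenaGeometry][rectangular_chamber] override;
#'   by default each file's sidecar geometry is used.
#' @param max_gap_frames gap-fill policy passed to [fill_gaps()].
#' @param exclusion_basis which phase's speed gates exclusion (see
#'   [score_assay()]).
#' @param adjust post-hoc adjustment (see [compare_groups()]).
#' @param seed integer seed recorded in every output.
#' @return A `RunConfig` list.
#' @export
run_config <- function(assay = c("preference", "shoaling"),
                       manifest, out_dir,
                       protocol = assay_protocol(), geometry = NULL,
                       max_gap_frames = 5L,
                       exclusion_basis = "test",
                       adjust = "benjamini_hochberg",
                       seed = 1L) {
  assay <- match.arg(assay)
  structure(
    list(assay = assay, manifest = manifest, out_dir = out_dir,
         protocol = protocol, geometry = geometry,
         max_gap_frames = max_gap_frames, exclusion_basis = exclusion_basis,
         adjust = adjust, seed = as.integer(seed)),
    class = "RunConfig"
  )
}

read_manifest <- function(manifest, id_col) {
  df <- if (is.data.frame(manifest)) {
    manifest
  } else {
    if (!file.exists(manifest)) stopf("manifest '%s' does not exist", manifest)
    read.csv(manifest, stringsAsFactors = FALSE)
  }
  required <- c("path", id_col, "genotype", "age_wpf")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stopf("manifest lacks required column(s): %s",
          paste(missing, collapse = ", "))
  }
  if (is.null(df$rearing)) df$rearing <- "social"
  df
}

log_line <- function(con, event, payload) {
  rec <- c(list(ts = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), event = event),
           payload)
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null"),
             con)
}

#' Run the social-preference batch pipeline
#'
#' For every manifest row: read the trajectory, fill short gaps, and compute
#' phase speeds. Exclusion is a two-pass batch procedure: first the mean
#' exclusion-basis speed of every genotype group within each age group, then
#' the per-age threshold (0.6 x smallest group mean) applied to each fish.
#' Included fish are compared per age group (genotype within age) with the
#' nonparametric chain.
#'
#' Per-file failures are logged and skipped; the run summary counts them.
#'
#' @param cfg a [run_config()] with `assay = "preference"`.
#' @return Invisibly, a list with `results` (per-fish table), `stats`
#'   (a [GroupComparison][compare_groups]), `thresholds` (per age group) and
#'   `log_path`. Tables are also written to `out_dir` as
#'   `preference_results.csv`, `stats_omnibus.csv`, `stats_pairwise.csv`,
#'   `thresholds.csv` and `run.log.jsonl`.
#' @export
run_preference_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"), cfg$assay == "preference")
  man <- read_manifest(cfg$manifest, "fish_id")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "run.log.jsonl")
  con <- file(log_path, "w")
  on.exit(close(con), add = TRUE)
  log_line(con, "config", list(assay = cfg$assay, seed = cfg$seed,
                               max_gap_frames = cfg$max_gap_frames,
                               exclusion_basis = cfg$exclusion_basis,
                               adjust = cfg$adjust,
                               n_manifest = nrow(man)))
  rows <- vector("list", nrow(man))
  failed <- 0L
  for (i in seq_len(nrow(man))) {
    rows[[i]] <- tryCatch({
      ts <- read_trajectories(man$path[i], geometry = cfg$geometry)
      ts <- fill_gaps(ts, cfg$max_gap_frames)
      sc <- score_assay(ts, cfg$protocol, threshold_mm_s = 0,
                        exclusion_basis = cfg$exclusion_basis)
      data.frame(
        fish_id = man$fish_id[i], genotype = man$genotype[i],
        age_wpf = man$age_wpf[i], rearing = man$rearing[i],
        percent_social = sc$percent_time_social,
        mean_speed_test = sc$mean_speed_test,
        mean_speed_habituation = sc$mean_speed_habituation,
        stringsAsFactors = FALSE
      )
    }, error = function(e) {
      failed <<- failed + 1L
      log_line(con, "file_error", list(path = man$path[i],
                                       message = conditionMessage(e)))
      NULL
    })
  }
  res <- do.call(rbind, rows)
  if (is.null(res) || nrow(res) == 0L) {
    stopf("no manifest row could be processed (see %s)", log_path)
  }
  # pass 2: per-age-group thresholds from genotype-group mean speeds
  basis_col <- switch(cfg$exclusion_basis,
                      test = "mean_speed_test",
                      habituation = "mean_speed_habituation",
                      min = NULL)
  basis <- if (is.null(basis_col)) {
    pmin(res$mean_speed_test, res$mean_speed_habituation)
  } else {
    res[[basis_col]]
  }
  thr_rows <- lapply(unique(res$age_wpf), function(a) {
    sel <- res$age_wpf == a
    means <- tapply(basis[sel], res$genotype[sel], mean)
    data.frame(age_wpf = a, threshold_mm_s = exclusion_threshold(means),
               n_groups = length(means))
  })
  thresholds <- do.call(rbind, thr_rows)
  res$threshold_mm_s <- thresholds$threshold_mm_s[
    match(res$age_wpf, thresholds$age_wpf)]
  res$included <- basis >= res$threshold_mm_s
  res$seed <- cfg$seed
  for (a in thresholds$age_wpf) {
    sel <- res$age_wpf == a
    log_line(con, "exclusion", list(
      age_wpf = a,
      threshold_mm_s = thresholds$threshold_mm_s[thresholds$age_wpf == a],
      n_included = sum(res$included[sel]),
      n_excluded = sum(!res$included[sel])
    ))
  }
  inc <- res[res$included, , drop = FALSE]
  stats <- NULL
  if (nrow(inc) && length(unique(inc$genotype)) >= 2L) {
    stats <- compare_groups(inc, "percent_social", "genotype",
                            family = "age_wpf", adjust = cfg$adjust)
    write.csv(stats$omnibus, file.path(cfg$out_dir, "stats_omnibus.csv"),
              row.names = FALSE)
    write.csv(stats$pairwise, file.path(cfg$out_dir, "stats_pairwise.csv"),
              row.names = FALSE)
  } else {
    log_line(con, "stats_skipped",
             list(reason = "fewer than 2 non-empty groups after exclusion"))
  }
  write.csv(res, file.path(cfg$out_dir, "preference_results.csv"),
            row.names = FALSE)
  write.csv(thresholds, file.path(cfg$out_dir, "thresholds.csv"),
            row.names = FALSE)
  log_line(con, "summary", list(n_processed = nrow(res), n_failed = failed,
                                n_included = sum(res$included)))
  invisible(list(results = res, stats = stats, thresholds = thresholds,
                 n_failed = failed, log_path = log_path))
}

#' Run the shoaling batch pipeline
#'
#' Computes one [shoal_metrics()] record per manifest row (one row per shoal
#' recording) and compares genotype groups within each age group for every
#' metric.
#'
#' @param cfg a [run_config()] with `assay = "shoaling"`.
#' @param metrics which metric columns to compare across groups.
#' @return Invisibly, a list with `metrics` (per-shoal table), `stats`
#'   (named list of [GroupComparison][compare_groups], one per metric) and
#'   `log_path`. Tables are written to `out_dir` as `shoal_metrics.csv` and
#'   `stats_<metric>_{omnibus,pairwise}.csv`, plus `run.log.jsonl`.
#' @export
run_shoaling_pipeline <- function(cfg,
                                  metrics = c("nnd_mm", "iid_mm", "fnd_mm",
                                              "cumulative_distance_mm",
                                              "variance_explained_2")) {
  stopifnot(inherits(cfg, "RunConfig"), cfg$assay == "shoaling")
  man <- read_manifest(cfg$manifest, "shoal_id")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "run.log.jsonl")
  con <- file(log_path, "w")
  on.exit(close(con), add = TRUE)
  log_line(con, "config", list(assay = cfg$assay, seed = cfg$seed,
                               max_gap_frames = cfg$max_gap_frames,
                               adjust = cfg$adjust, n_manifest = nrow(man)))
  rows <- vector("list", nrow(man))
  failed <- 0L
  for (i in seq_len(nrow(man))) {
    rows[[i]] <- tryCatch({
      ts <- read_trajectories(man$path[i], geometry = cfg$geometry)
      ts <- fill_gaps(ts, cfg$max_gap_frames)
      sm <- shoal_metrics(ts)
      cbind(data.frame(shoal_id = man$shoal_id[i], genotype = man$genotype[i],
                       age_wpf = man$age_wpf[i], rearing = man$rearing[i],
                       stringsAsFactors = FALSE),
            sm[, setdiff(names(sm), "source_id")])
    }, error = function(e) {
      failed <<- failed + 1L
      log_line(con, "file_error", list(path = man$path[i],
                                       message = conditionMessage(e)))
      NULL
    })
  }
  res <- do.call(rbind, rows)
  if (is.null(res) || nrow(res) == 0L) {
    stopf("no manifest row could be processed (see %s)", log_path)
  }
  res$seed <- cfg$seed
  write.csv(res, file.path(cfg$out_dir, "shoal_metrics.csv"),
            row.names = FALSE)
  stats <- list()
  if (length(unique(res$genotype)) >= 2L) {
    for (m in metrics) {
      gc <- compare_groups(res, m, "genotype", family = "age_wpf",
                           adjust = cfg$adjust)
      stats[[m]] <- gc
      write.csv(gc$omnibus,
                file.path(cfg$out_dir, sprintf("stats_%s_omnibus.csv", m)),
                row.names = FALSE)
      write.csv(gc$pairwise,
                file.path(cfg$out_dir, sprintf("stats_%s_pairwise.csv", m)),
                row.names = FALSE)
    }
  } else {
    log_line(con, "stats_skipped", list(reason = "fewer than 2 genotype groups"))
  }
  log_line(con, "summary", list(n_processed = nrow(res), n_failed = failed))
  invisible(list(metrics = res, stats = stats, n_failed = failed,
                 log_path = log_path))
}
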