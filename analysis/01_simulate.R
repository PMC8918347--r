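#!/usr/bin/env Rscript

# Step 1: build the synthetic study cohorts used by the downstream drivers.
#
# Preference cohort: 3 "genotype" groups of 15 fish at 4 wpf with planted
# social bias (wt and ko_null unbiased; ko_social drifts toward the stimulus
# wall at 2 x step-SD per second = 1 mm/s), plus 2 frozen fish per group to
# exercise the speed-based exclusion rule. A shortened protocol (60 s
# habituation, 120 s test, last 100 s analyzed) keeps the files small; the
# full-length protocol is exercised in the package tests.
#
# Shoaling cohort: 10 shoals of 20 fish per group under the shared-motion
# model, coordinated (rho = 0.8) vs poorly coordinated (rho = 0.3), 60 s at
# 30 fps.
#
# Writes trajectories + manifests under results/simdata/.

suppressMessages(library(shoalkit))

seed <- 1234
out <- "results/simdata"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

## ---- preference cohort ------------------------------------------------------
geom <- rectangular_chamber(25, 75, 8, 75, "left")
proto_s <- c(habituation = 60, test = 120, analysis_last = 100)
fps <- 20
betas <- c(wt = 0, ko_null = 0, ko_social = 2 * 0.5)  # mm/s
n_per_group <- 15
frozen_per_group <- 2

rows <- list(); k <- 0L
for (gt in names(betas)) {
  for (i in seq_len(n_per_group)) {
    k <- k + 1L
    id <- sprintf("%s_%02d", gt, i)
    path <- file.path(out, paste0("pref_", id, ".csv"))
    if (i <= frozen_per_group) {
      T <- sum(proto_s[c("habituation", "test")]) * fps
      ts <- trajectory_set(cbind(rep(6, T)), cbind(rep(40, T)), fps, geom,
                           fish_ids = id, source_id = id)
    } else {
      ts <- simulate_preference_fish(preference_sim_params(
        geom, bias_mm_s = betas[[gt]], step_sd_mm = 0.5, frame_rate_hz = fps,
        duration_s = sum(proto_s[c("habituation", "test")]),
        seed = seed + k))
    }
    write_trajectories(ts, path)
    rows[[k]] <- data.frame(path = path, fish_id = id, genotype = gt,
                            age_wpf = 4, rearing = "social")
  }
}
pref_manifest <- do.call(rbind, rows)
write.csv(pref_manifest, file.path(out, "preference_manifest.csv"),
          row.names = FALSE)
cat(sprintf("preference cohort: %d fish (%d frozen) -> %s\n",
            nrow(pref_manifest), 3 * frozen_per_group, out))

## ---- shoaling cohort --------------------------------------------------------
rhos <- c(wt = 0.8, ko = 0.3)
n_shoals <- 10
rows <- list(); k <- 0L
for (gt in names(rhos)) {
  for (i in seq_len(n_shoals)) {
    k <- k + 1L
    id <- sprintf("%s_shoal%02d", gt, i)
    path <- file.path(out, paste0("shoal_", id, ".csv"))
    ts <- simulate_shared_motion_shoal(shared_motion_params_rho(
      rhos[[gt]], n_fish = 20, duration_s = 60, frame_rate_hz = 30,
      seed = seed + 10000 + k))
    write_trajectories(ts, path)
    rows[[k]] <- data.frame(path = path, shoal_id = id, genotype = gt,
                            age_wpf = 8, rearing = "social")
  }
}
shoal_manifest <- do.call(rbind, rows)
write.csv(shoal_manifest, file.path(out, "shoaling_manifest.csv"),
          row.names = FALSE)
cat(sprintf("shoaling cohort: %d shoals of 20 fish -> %s\n",
            nrow(shoal_manifest), out))
cat(sprintf("ground truth: preference bias %s mm/s; coordination rho %s\n",
            paste(betas, collapse = "/"), paste(rhos, collapse = "/")))
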