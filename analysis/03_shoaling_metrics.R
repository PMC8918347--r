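#!/usr/bin/env Rscript

# Step 3: shoal metrics and group comparison for the shoaling cohort.
#
# One record per shoal: NND/IID/FND (mm), cumulative shoal distance (mm)
# and the variance explained by the first two PCs of the 40-row trajectory
# matrix. Genotype groups are compared per metric with the nonparametric
# chain. Expects results/simdata from 01_simulate.R; writes tables under
# results/shoaling/.

suppressMessages(library(shoalkit))

man <- "results/simdata/shoaling_manifest.csv"
if (!file.exists(man)) stop("run analysis/01_simulate.R first")

cfg <- run_config(assay = "shoaling", manifest = man,
                  out_dir = "results/shoaling", seed = 1234)
run <- run_shoaling_pipeline(cfg)

met <- run$metrics
cat(sprintf("computed metrics for %d shoals\n", nrow(met)))
agg <- aggregate(met[c("nnd_mm", "iid_mm", "fnd_mm",
                       "cumulative_distance_mm", "variance_explained_2")],
                 by = list(genotype = met$genotype), mean)
print(agg, digits = 3)
cat("\nvariance explained, group comparison:\n")
print(run$stats$variance_explained_2)
cat("\nThe coordinated group (rho = 0.8) should show markedly higher",
    "variance explained than the rho = 0.3 group. Group spacing differs",
    "too: with the total motion scale fixed, spacing tracks the",
    "idiosyncratic spread sqrt(1 - rho) * sigma_total, so the poorly",
    "coordinated group is also the looser one. Cumulative distance is",
    "comparable because both groups share the same total motion scale.\n")
cat("tables in results/shoaling/\n")
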