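#!/usr/bin/env Rscript

# Step 2: score the social-preference cohort and compare genotype groups.
#
# Runs the two-pass batch pipeline: per-fish ROI scoring and phase speeds,
# per-age exclusion threshold (0.6 x smallest genotype-group mean speed),
# then Kruskal-Wallis + post-hoc rank-sum (BH-adjusted) on the included
# fish. Expects results/simdata from 01_simulate.R; writes tables under
# results/preference/.

suppressMessages(library(shoalkit))

man <- "results/simdata/preference_manifest.csv"
if (!file.exists(man)) stop("run analysis/01_simulate.R first")

cfg <- run_config(
  assay = "preference", manifest = man, out_dir = "results/preference",
  protocol = assay_protocol(habituation_s = 60, test_s = 120,
                            analysis_last_s = 100),
  seed = 1234
)
run <- run_preference_pipeline(cfg)

res <- run$results
cat(sprintf("scored %d fish; %d excluded at threshold %.2f mm/s\n",
            nrow(res), sum(!res$included), run$thresholds$threshold_mm_s[1]))
inc <- res[res$included, ]
means <- tapply(inc$percent_social, inc$genotype, mean)
cat("mean % time in social ROI (included fish):\n")
print(round(means, 1))
cat("\nomnibus + post-hoc:\n")
print(run$stats)
cat("\nThe planted social bias (ko_social) should be the only group near",
    "100% and the only significant post-hoc contrast.\n")
cat("tables in results/preference/\n")
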