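---
title: "Quantifying zebrafish social preference and shoaling from trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying zebrafish social preference and shoaling from trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shoalkit)
```

shoalkit quantifies two canonical assays of zebrafish sociality from 2-D
tracking trajectories: the **social preference test** (a single fish choosing
between a chamber half adjacent to visible conspecifics and the opposite
half) and the **shoaling assay** (a group of 20 fish swimming freely in a
circular arena). This vignette documents the underlying models, the
parameters that matter, the numerical decisions, and what the synthetic
generators do and do not emulate.

## The trajectory data model

All analyses consume a `TrajectorySet`: positions of N fish over T frames at
a fixed frame rate, in **mm**, with tracking dropouts as explicit missing
samples (`NA` in both coordinates). Conventions:

* The origin sits at the lower-left corner of the test area (rectangular
  chamber) or of the arena's bounding square (circular arena); x grows
  rightward, y upward. Stimulus areas of the preference chamber lie outside
  the `[0, test_width]` range on the occupied side.
* Frames are indexed from 0 and every window is half-open `[start, end)`.
* Pixel-to-mm conversion happens at ingest via the optional `px_per_mm`
  field of the JSON metadata sidecar; internally everything is mm.

Swim speed is computed from **consecutive-frame displacements only, without
smoothing**: the mean Euclidean step length over tracked frame pairs, times
the frame rate. Pairs spanning a dropout are excluded from numerator and
denominator alike, so a gap neither inflates (by bridging) nor deflates (by
zero-filling) the estimate.

**Gap policy.** Trackers drop samples during occlusions and reflections; how
such gaps should be repaired before metric computation is an open choice.
`fill_gaps()` linearly interpolates gaps up to `max_gap_frames` (default 5
frames, about 0.17 s at 30 fps — short enough that linear interpolation
cannot invent a turn a fish could not have made), and leaves longer and
leading/trailing gaps missing. Every downstream metric also tolerates
remaining gaps explicitly, so filling is an optional convenience, not a
requirement.

## Social preference

The chamber has a rectangular test area (25 × 75 mm for 2–4-week-old fish,
50 × 75 mm at 8 weeks) flanked by two stimulus areas (8 × 75 / 16 × 75 mm)
behind transparent walls. The protocol is 10 min habituation without
stimulus fish, then a 12 min test phase with two stimulus fish in one
stimulus area; scoring uses the **last 10 min** of the test because freshly
transferred stimulus fish need up to 2 min to behave normally.

`build_rois()` splits the test area at the midline perpendicular to its
long axis: the half adjacent to the occupied stimulus area is the *social
ROI*, the other the *antisocial ROI*. Tie rule: a point exactly on the
midline counts as social, points on outer walls count as inside. This makes
scoring deterministic; on continuous positions the affected set has measure
zero, and the two ROIs always partition the test area, so social and
antisocial percentages sum to 100 on gap-free data.

Two decisions the assay description leaves open:

* **Percent of what?** With dropouts, time in the social ROI is reported as
  a percentage of *tracked* frames in the window, not of all frames. A
  dropout carries no information about where the fish was; counting it as
  "not social" would bias scores downward in proportion to tracking quality.
* **Which speed gates exclusion?** Both habituation- and test-phase speeds
  are computed. The default gates on the *test-phase* speed (freezing during
  the scored phase is what invalidates the score); `exclusion_basis` can be
  set to `"habituation"` or `"min"`.

**Exclusion rule.** Fish with reduced motion (freezing) are excluded with a
threshold computed per age group: 0.6 × the smallest genotype-group mean
speed. This is a two-pass batch procedure (`run_preference_pipeline()`):
group means first, threshold second, per-fish flags third. A fish exactly at
the threshold is **included** (`>=` rule). Note a degenerate corner: if an
entire group freezes, its mean is 0, the threshold is 0, and the `>=` rule
includes everyone — the rule is relative, and has no absolute floor.

## Shoaling metrics

For N ≥ 2 fish, per frame and focal fish, the distances to all other
tracked fish give the **nearest-neighbor** (min), **inter-individual**
(mean) and **farthest-neighbor** (max) distance; `nnd ≤ iid ≤ fnd` holds by
construction. Per-fish values are time averages; the shoal-level value is
the mean over fish. For the IID this focal-fish convention equals the mean
over unordered pairs on complete data; both are reported
(`iid_mm`, `iid_pair_mm`). Frames where a pair is untracked are dropped
pairwise.

**Cumulative shoal distance** is the sum of per-fish path lengths — the
standard total-activity proxy; a centroid-path alternative sits behind
`method = "centroid"`.

**Polarization via the trajectory matrix.** The x- and y-components of all
trajectories are stacked into a 2N × T matrix (fish-major row order; a
gap-free 20-fish, 30-min, 30-fps recording gives the canonical 40 × 54,000
matrix). Rows are centered by their time means and the 2N × 2N sample
covariance (unbiased, T−1 denominator; covariance, **not** correlation — the
statistic is about shared displacement, and rows share units) is eigen
decomposed. The statistic is

$$\mathrm{VE}_2 = \frac{\lambda_1 + \lambda_2}{\sum_{r=1}^{2N} \lambda_r} \in [1/N,\, 1].$$

When the shoal moves as one, the two leading components are the x/y motion
of the shoal centroid and VE₂ approaches 1; for independent fish it
approaches 1/N. Frames with any missing sample are dropped listwise before
the covariance — interpolating inside the PCA would fabricate covariance
between fish; if filling is wanted it must be an explicit, upstream
`fill_gaps()` call.

**Mixed-movie control.** `mixed_shoal_control()` composes pseudo-shoals of
`k_same` fish from one recording plus `20 − k_same` fish drawn one each from
distinct other recordings. Fish recorded separately cannot be coordinated,
so VE₂ sits near 1/N at `k_same = 0` and rises continuously to the
true-shoal value at `k_same = 20`. This is the sanity check that VE₂
measures coordination rather than some per-recording artifact.

## The shared-motion generator and its closed form

`simulate_shared_motion_shoal()` writes fish i's position at frame t as
$\mathbf{p}_i(t) = \mathbf{c}_0 + \mathbf{c}(t) + \mathbf{e}_i(t)$, where the
shared process c and the per-fish processes e_i are independent stationary
mean-reverting (discrete Ornstein–Uhlenbeck) walks per coordinate with
stationary SDs σ_shared and σ_idio. The coordination level is
ρ = σ²_shared / (σ²_shared + σ²_idio).

Per axis the population covariance across fish is σ²_shared·J + σ²_idio·I,
with top eigenvalue N·σ²_shared + σ²_idio and the remaining N−1 equal to
σ²_idio. The top two of the 2N eigenvalues are the two axis copies of the
top one, so

$$\mathrm{VE}_2^{\mathrm{pop}} = \rho + \frac{1-\rho}{N},$$

implemented as `expected_variance_explained()`. Stationarity is the point
of the mean-reverting choice: pure random walks have no stationary
covariance, so "variance explained" would depend on the observation window.

**Relaxation time.** The OU relaxation time (default `relaxation_s = 0.1`)
sets the trade-off between path smoothness and estimator accuracy. An AR(1)
with coefficient a = exp(−1/(τ·fps)) yields roughly
T·(1−a²)/(1+a²) effectively independent frames; the top sample eigenvalues
of a p-dimensional covariance estimated from n_eff such frames are inflated
by about (1 + √(p/n_eff))². At τ = 0.1 s a 30-min, 30-fps recording gives
n_eff ≈ 17,000 for p = 40, keeping the bias of VE₂ below ~0.005 at ρ = 0 —
inside the ±0.01 band the convergence tests demand. A cinematic τ of
seconds would look smoother but pushes n_eff below 10³ and the ρ = 0 bias
above 0.02: the generator is an estimator test-bed first and a screensaver
second. Boundary reflection is **off** by default so the closed form is
exact (wandering outside the arena is possible but irrelevant to the
statistic and rare at the default scales: σ_total = 30 mm around the center
of a 700 mm arena); it can be enabled for display purposes.

All generators consume a single integer seed from which every process is
drawn in a fixed order, so runs are bit-reproducible; the caller's RNG
stream is saved and restored.

## The zonal generator

`simulate_zonal_shoal()` is the classic three-zone agent model for
qualitative realism: each fish turns away from neighbors inside the
repulsion radius; otherwise it averages headings of neighbors inside the
alignment radius and steers toward neighbors in the shell between the
alignment and attraction radii, with Gaussian heading noise, constant speed
and a reflecting circular wall. Defaults (repulsion 15 mm, alignment 60 mm,
attraction 250 mm, 50 mm/s, noise SD 0.25 rad at 30 fps) produce cohesive,
loosely polarized shoals at 8-week body sizes.

One subtlety worth recording: with infinite heading noise the fish become
independent, but their **positions** are random walks — non-stationary, with
an arena-mixing time far beyond a 30-min recording — so positional VE₂ does
not converge to 1/N at feasible T. The independence limit is instead checked
on the per-frame step increments, which are stationary and mix immediately;
there VE₂ → 1/N at rate 1/T, and strong alignment drives step-level VE₂
toward 1.

## The preference generator

`simulate_preference_fish()` is a biased random walk in the test area:
per-frame isotropic Gaussian step (SD `step_sd_mm`, default 0.5 mm) plus a
constant drift `bias_mm_s / frame_rate_hz` toward the stimulus wall, with
reflecting boundaries. At the 20 fps default the step SD gives a mean speed
of ≈ 12.5 mm/s, in the range young zebrafish actually swim. `bias_mm_s = 0`
is exactly symmetric, so the expected social-ROI time is 50% — the key
calibration point — and the expected percentage increases monotonically with
the bias. A reflected walk with constant drift δ per frame equilibrates to
an approximately exponential density with length scale σ²/(2δ) from the
stimulus wall, which is what makes the bias→percentage mapping steep:
`bias_mm_s` of 1–2 already pins fish above 90%.

## Statistical chain

Assay scores are typically non-normal (bounded percentages, skewed
distances), so group comparisons are nonparametric throughout, two-sided:

* `ks_normality()` — the Kolmogorov–Smirnov statistic against a normal with
  the sample's mean/SD. Because the parameters are estimated from the same
  sample, the classical KS null is wrong (conservative); the default uses
  the Lilliefors null, the parametric variant is available for comparison.
* `kruskal_wallis()` — tie-corrected H; chi-square p-value with g−1 df, or
  an exact permutation p `P(H ≥ H_obs)` over all group assignments,
  selected automatically for total n ≤ 10.
* `rank_sum()` — Mann–Whitney U / Wilcoxon rank-sum; exact null when
  tie-free and total n ≤ 25, otherwise tie-corrected normal approximation
  with continuity correction.
* `compare_groups()` — per comparison family (e.g. genotype-within-age): the
  omnibus first, post-hoc pairwise tests only when the omnibus is
  significant ("followed by"), Benjamini–Hochberg adjustment per family by
  default. BH is a deliberate default, not a claim about any particular
  published analysis; `adjust = "none"` yields raw p-values. Stars follow
  the conventional 0.05 / 0.01 / 0.001 thresholds.

## What passing tests do and do not show

The generators are designed so that every estimator has a known target:
closed-form VE₂, 50% symmetry, planted group differences, exact enumeration
for the rank tests. Passing tests therefore show that the **estimators and
the pipeline are correct** — not that real fish behave like the generators.
Features of real data the synthetic module deliberately omits: burst-glide
(bout-structured) swimming, wall-following/thigmotaxis, body shape and
collision constraints, inter-fish interaction in the preference assay
(stimulus fish are not modeled, only their effect as a drift), and
occlusion-driven (hence spatially correlated) tracking dropouts — simulated
dropouts are random in time. Conclusions about biology always require real
trajectories; the package's job is to make the numbers computed from them
trustworthy.

## Problem sizes used by the checks

The convergence and control checks run at the assay's native scale — 20
fish, 30 min at 30 fps (a 40 × 54,000 matrix) for the variance-explained
grid, 21 recordings of 10 min for the mixed-movie curve, 2,000 null and 500
shifted replicates for calibration and power, 200 full-protocol walks for
the 50% symmetry point. The narrative drivers under `analysis/` use
shortened recordings (60–180 s) so a complete desk run stays in seconds;
their purpose is demonstration, and every quantitative guarantee lives in
the tests at full scale.

## Known limitations

* The VE₂ estimator inherits the usual top-eigenvalue inflation of sample
  covariances; at the canonical recording length the bias is below 0.005,
  but for substantially shorter recordings or much larger shoals it grows
  like (1 + √(p/n_eff))² − 1 and should be kept in mind when comparing
  groups with different recording lengths (the pipeline truncates mixed
  compositions to a common length for exactly this reason).
* The exclusion rule is relative per age group and has no absolute floor
  (see above).
* `read_trajectories()` expects the documented CSV dialect; exports from
  specific trackers need a one-off conversion to
  `frame,fish_id,x_mm,y_mm` plus the JSON sidecar.
* The exact Kruskal–Wallis permutation is enumerative and limited to total
  n ≤ 12; beyond that the chi-square approximation is used (its calibration
  at the study's group sizes is verified by simulation in the test suite).
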