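Package: shoalkit
Title: Trajectory-Based Quantification of Zebrafish Social Preference and Shoaling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying social behavior of zebrafish (Danio rerio)
    from multi-animal tracking trajectories. Implements the social-preference
    assay analysis (region-of-interest time scoring with a speed-based
    exclusion rule), shoal cohesion and polarization metrics (nearest-,
    inter-individual- and farthest-neighbor distances, cumulative shoal
    distance, and the trajectory-matrix PCA "variance explained" coordination
    statistic with its mixed-movie randomization control), synthetic
    trajectory generators with known ground-truth coordination and social
    bias, and the nonparametric group-comparison chain (Kolmogorov-Smirnov
    normality screen, Kruskal-Wallis omnibus, post-hoc Wilcoxon rank-sum with
    optional Benjamini-Hochberg adjustment).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    nortest,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
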