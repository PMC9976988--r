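Package: taskgrad
Title: Multiscale Profiling of Task fMRI Effects Across Functional Systems
    and the Principal Connectivity Gradient
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maps task-fMRI activation and deactivation across canonical
    resting-state functional systems and along the principal functional
    connectivity gradient. Extracts parcel-wise contrast estimates from
    volumetric beta maps, builds covariate-adjusted system and gradient-bin
    profiles, computes normative Z-score deviation maps of patients against
    controls, and performs permutation-based inference: sign-flip one-sample
    and label-exchange two-sample tests with Benjamini-Hochberg false
    discovery rate control, Cohen's d effect sizes, an area-between-curves
    global test for gradient-stratified profiles, and permutation
    correlations with nuisance covariates. Includes cohort-description
    statistics (Pearson chi-square, Fisher's exact test, one-way ANOVA from
    summaries, Kruskal-Wallis, ANCOVA), motion-based quality control, a
    synthetic parcel-level cohort generator for three-group designs, and a
    reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
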