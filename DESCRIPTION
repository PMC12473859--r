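Package: comgait
Title: Center-of-Mass Gait Dynamics and Body-Composition Correlation
    Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying mobility in older adults from
    vision-based pose estimation. Reads 17-keypoint pose time series,
    repairs low-confidence frames, computes center-of-mass (CoM)
    trajectories, per-frame center displacement and directional shift,
    and cleans the displacement stream with percentile thresholds.
    Ingests bioimpedance body-composition tables with consistency
    validation and AWGS 2019 sarcopenia-risk screening, scores the
    4-metre SPPB walking test, and runs the full statistical battery
    (Shapiro-Wilk screening, Pearson/Spearman correlation matrices with
    significance markers, per-indicator simple regressions, sex-stratified
    analyses). A seeded synthetic-cohort generator with planted
    correlations makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
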