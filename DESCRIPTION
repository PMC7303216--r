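Package: microstatr
Title: EEG Microstate Segmentation, Temporal Dynamics and Meta-Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Resting-state EEG microstate analysis: global field power
    (GFP) computation and peak extraction, polarity-invariant modified
    k-means clustering of peak topographies with two-level
    (individual-to-group) aggregation, competitive backfitting with
    Besag-penalty temporal smoothing and single-frame rejection,
    per-class temporal parameters (mean duration, coverage, occurrence),
    group statistics (chi-square, mixed-design ANOVA with covariates,
    effect sizes, Bonferroni-Holm correction, BIC Bayes factors), and
    restricted maximum likelihood (REML) random-effects meta-analysis of
    Hedges' g. Includes a semi-Markov surrogate EEG generator with
    planted microstate dynamics for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
RoxygenNote: 7.3.3
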