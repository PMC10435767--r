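Package: glycanclock
Title: IgG Glycan Biological-Ageing Clock Analysis for Case-Control Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for immunoglobulin G (IgG) N-glycan ageing
    studies in case-control cohorts: total-area normalization of UHPLC glycan
    peak tables, log transformation, empirical-Bayes (ComBat-style) plate
    batch correction, peak exclusion, derived glycosylation traits
    (G0/G1/G2/S/F/B), rank-based inverse-normal transformation, per-cohort
    general linear models and sibling-paired mixed models, fixed-effects
    meta-analysis with Benjamini-Hochberg control, per-group linear age
    trends with a parallel-slopes test, the glycan-age shift estimate (the
    horizontal offset in years between case and control trend curves) with
    bootstrap confidence intervals, and PCA-based placement of singleton
    samples relative to group clusters. A synthetic cohort generator
    reproduces the statistical structure the analysis assumes (linear age
    trends, group offsets, compositional closure, plate effects, sibling
    pairs) so every stage is testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    purrr,
    rlang,
    readr,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    metafor,
    sva,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
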