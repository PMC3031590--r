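Package: cortnet
Title: Weighted Cortical Functional Network Efficiency Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Construction and analysis of weighted cortical functional
    networks from parcellated regional response matrices. Builds zero-lag
    Pearson correlation matrices, thresholds them to fixed-cost weighted
    graphs, computes Latora-Marchiori global and local efficiency on
    reciprocal-weight shortest paths, normalizes the measures against
    degree-preserving Maslov-Sneppen surrogate ensembles, and compares
    cost-averaged measures across groups and task conditions with a
    repeated-measures mixed ANOVA, covariate correlations gated by
    Shapiro-Wilk normality tests, and head-motion controls. Includes a
    synthetic cohort generator that emulates the statistical structure of a
    two-group, two-condition speech-perception fMRI study (modular
    small-world coupling, planted group and interaction effects, cortical
    thickness and task-accuracy covariates) so the full pipeline is testable
    without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
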