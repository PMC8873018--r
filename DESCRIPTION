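Package: surflmm
Title: Vertex-Wise Longitudinal Mixed Models for Cortical Surface Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mass-univariate analysis of longitudinal surface-based
    morphometry data. Fits per-vertex polynomial random-slope linear mixed
    models by maximum likelihood, selects the model order per vertex with
    the Bayesian Information Criterion, tests group and group-by-age
    (trajectory shape) effects with likelihood-ratio tests, corrects for
    multiple comparisons with cluster-wise Monte-Carlo permutation on the
    triangulated mesh, and evaluates age-resolved maps of group trajectory
    differences and annualized rates of change. Includes readers for
    FreeSurfer surface, curv and MGH files, a synthetic longitudinal cohort
    simulator with planted effect clusters for validation, and an
    end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
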