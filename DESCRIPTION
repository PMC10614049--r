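Package: cfimpact
Title: Quasi-Experimental Evaluation of Community-Forest Conservation Effectiveness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating the forest-conservation effectiveness of
    community forests (CFs) and similar zoning interventions from annual tree
    canopy cover (TCC) and land-cover panels. Implements the full
    quasi-experimental chain: raster-derived confounders (terrain, access,
    initial forest condition), phased exact plus propensity-score matching by
    establishment year with standardized-mean-difference balance screening,
    event-time realignment and treated-minus-control difference series,
    interrupted time-series (segmented) regression, establishment-year cohort
    regressions, and Mann-Kendall trend screens with Bonferroni correction.
    Ships a synthetic-landscape generator with known injected effects so the
    whole chain is exercisable and validated by parameter recovery at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    glmnet,
    yaml,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    sandwich
Config/testthat/edition: 3
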