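Package: connectodev
Title: Construction and Developmental Analysis of Structural Brain Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building structural brain networks from tractography
    streamlines and a labeled parcellation, and for analysing their development
    in case-control cohorts. Builds binary, FA-weighted and total-strength
    normalized connectomes; computes integration and segregation graph metrics
    (degree, strength, global and local efficiency, clustering coefficient);
    performs covariate-adjusted group comparisons via general linear models,
    age-residualized partial correlations between network metrics and
    neurobehavioral scores, and second-order polynomial developmental
    trajectory fits. A fully seeded synthetic-cohort generator emulates a
    two-group (control vs. growth-restricted) design at 1, 6 and 10 years of
    age so that the whole pipeline can be exercised without imaging data.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    igraph,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
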