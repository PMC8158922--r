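Package: yoyrockfish
Title: Spatiotemporal Analysis of Pelagic Juvenile Rockfish Survey Catches
Version: 0.1.0
Authors@R:
    person("Survey", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing haul-level midwater-trawl catches of pelagic
    young-of-the-year (YOY) rockfish: quality control and station assignment
    for multi-survey haul tables, station-level log-CPUE climatologies and
    z-score anomaly surfaces with inverse-distance-weighted interpolation,
    per-region delta-GLM (hurdle) index standardization with AIC covariate
    selection, dynamic factor analysis of regional index matrices by maximum
    likelihood (Kalman smoother plus ECME) with an AICc model grid and
    varimax-rotated loadings, PCA cross-validation of the latent trends, and
    NMDS ordination of the species assemblage with a fitted latitude surface.
    A synthetic-data generator reproduces the statistical structure of the
    survey (zero-inflated lognormal catches driven by latent AR(1) regional
    trends and a latitude-graded species composition) with known ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    vegan,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
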