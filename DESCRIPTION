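Package: stfield
Title: Spatiotemporal Exposure Prediction for Unbalanced Air-Monitoring Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hierarchical Gaussian spatiotemporal modeling of two-week average
    air pollutant concentrations measured on unbalanced multi-tier monitoring
    networks (regulatory, fixed, rotating home, and clustered snapshot sites).
    Log concentrations are decomposed into a covariate-driven long-term spatial
    mean, spatially varying coefficients on empirically estimated smooth time
    trends, and a temporally independent, spatially correlated residual.
    Includes partial least squares reduction of geographic covariates,
    maximum-likelihood estimation exploiting the model's low-rank/block
    covariance structure, universal-kriging prediction with back-transformation
    to concentration scale and long-term averaging, site-type-stratified
    cross-validation with MSE-based R-squared metrics, model selection over a
    candidate grid, and a synthetic campaign generator emulating the unbalanced
    monitoring design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    splines,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
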