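Package: quindex
Title: Quantile Index Biomarkers from Clustered Single-Cell Intensities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Supervised derivation of quantile-index (QI) biomarkers from
    clustered single-cell signal intensities. Converts nested
    subject/cluster/cell intensity tables into subject-level empirical
    quantile functions on a shared probability grid, fits penalized
    scalar-on-function regression models (linear functional terms and
    tensor-product bivariate smooths; gaussian, binomial and Cox
    likelihoods), and evaluates the resulting sign-adjusted integrand
    surface to compute linear (QI) and nonlinear (nlQI) quantile-index
    predictors on training or independent test data. Includes a
    synthetic-data generator with known ground truth, visualization of
    integrand surfaces with per-subject integration paths, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    pROC,
    splines,
    stats,
    survival,
    tools,
    utils,
    yaml
Suggests:
    mgcv,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
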