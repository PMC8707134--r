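Package: spatspec
Title: Spatially Aware Mixed-Model Analysis of Plot-Trial Hyperspectral Reflectance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for detecting treatment effects on leaf
    hyperspectral reflectance measured in small plot trials, where residuals
    are spatially autocorrelated. Provides spectral preprocessing (splice
    correction, 10-nm binning, multiplicative scatter correction,
    Savitzky-Golay smoothing), correlation-matrix principal component
    analysis with VARIMAX rotation and salient-band selection, per-component
    diagnostics (composite normality tests, Blom rank-normal scores,
    Levene's test, Moran's I and Geary's c), empirical semivariograms with
    weighted least-squares fitting of nugget and spherical models, and a
    REML-estimated linear mixed model with spherical residual covariance,
    generalized least-squares fixed effects, Wald F tests and pairwise
    least-squares-mean contrasts. A synthetic-data module generates
    split-plot trial designs, Gaussian random fields with known variogram
    structure, and latent-component-driven spectra so the whole pipeline can
    be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    Matrix,
    nortest,
    withr
Suggests:
    testthat (>= 3.0.0),
    ape,
    nlme,
    car,
    emmeans,
    optparse,
    jsonlite
Config/testthat/edition: 3
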