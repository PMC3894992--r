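Package: answers
Title: Non-Stationary Weibull Error Regression with Spatial Enhancement for
    Visual Field Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects deterioration (and improvement) in standard automated
    perimetry visual field series. Measurement error is modelled as a
    per-sensitivity-level mixture of Weibull distributions fitted to
    test-retest data by expectation-maximisation, capturing the
    non-stationary, skewed and censored variability of differential light
    sensitivity. Per-location linear trends are estimated by maximum a
    posteriori regression under a multivariate normal prior whose covariance
    encodes retinal nerve-fibre anatomy (hemifield-blocked spatial
    correlation), with a Laplace approximation supplying slope uncertainty.
    Global deterioration and improvement indices summarise the per-location
    probabilities of no deterioration. Includes the comparator methods
    (mean-deviation regression, point-wise linear regression with contiguity
    criteria), a false-positive-calibrated evaluation protocol based on
    reordered pseudo-series, and a synthetic data generator for test-retest
    pairs and progressing cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
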