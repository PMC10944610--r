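Package: fpcreg
Title: Functional Principal Component Regression for Intensive Longitudinal Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating a scalar health outcome to a sparsely and
    irregularly observed longitudinal predictor via functional principal
    component regression. Individual smooth trajectories are recovered from
    noisy intensive longitudinal data by sparse functional principal
    component analysis (penalized tensor-product spline covariance
    smoothing, discretized eigenanalysis, conditional-expectation scores),
    the outcome is regressed on the leading component scores, and the
    time-varying coefficient function is reconstructed with pointwise
    confidence bands. Includes preprocessing for long-format device data
    (label filtering, daily deduplication, window alignment, eligibility),
    leave-one-subject-out cross-validation, and a synthetic study generator
    with known ground truth emulating a daily self-monitored glucose to
    HbA1c design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    splines,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
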