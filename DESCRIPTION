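Package: pcmlink
Title: True-Score Equating of Polytomous Scales with the Partial Credit Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for linking two patient-reported-outcome scales answered by
    the same respondents (a common person design) through true-score equating
    under the partial credit model. Provides marginal-maximum-likelihood
    estimation of unidimensional and two-dimensional partial credit models
    with slopes fixed at one, concurrent calibration, anchored raw-score to
    ability lookup tables via test-characteristic-curve inversion,
    bidirectional concordance (crosswalk) tables, a Rasch model-fit battery
    (infit/outfit, threshold ordering, local dependency, residual-based
    dimensionality), transformation-precision statistics (RMSE, NRMSE,
    percent bias, mean-squared-error decomposition), and a Monte-Carlo study
    runner that simulates two correlated three-category scales under a
    configurable grid of construct similarity, targeting and difficulty-shift
    conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
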