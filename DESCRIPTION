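Package: savor
Title: Boosted Anticipatory-Utility Choice Models and Model-Based fMRI Regressors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits a computational model of choice in which the utility of
    anticipating a delayed reward (savoring) is boosted by the magnitude of the
    reward-prediction error elicited by advance information. Cue and target
    values are computed in closed form from a self-consistent prediction-error
    equation with an explicit stability bound on the boosting gain. Subject
    parameters are estimated by hierarchical Bayesian expectation-maximization
    with per-subject Laplace approximations, and model variants are compared by
    the integrated Bayesian information criterion estimated by sampling from the
    fitted group prior. The package also generates the model's predicted
    time-varying signals, convolves them with a canonical hemodynamic response
    function into GLM design matrices (including PPI regressors), and provides a
    Fourier phase-randomization test with max-statistic familywise-error
    correction, together with synthetic task, choice and BOLD generators for
    end-to-end simulation studies.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
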