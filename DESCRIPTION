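Package: asymstroke
Title: Hemispheric-Asymmetry CT Infarct Volumetry and Network Analysis of
    Post-Stroke Language Outcomes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Semi-automated infarct volumetry from non-contrast head CT by
    hemispheric asymmetry (reorientation, CT skull stripping, isotropic
    resampling, HU windowing, rigid registration of the left-right flipped
    image, 98th-percentile difference-map thresholding and cluster-size
    filtering), together with the downstream cohort analysis used to study
    post-stroke language deterioration: group screening with Welch t / Yates
    chi-square / Fisher tests and bias-corrected effect sizes, L1-regularized
    predictor selection with ROC (DeLong) and decision-curve validation, and
    GLASSO partial-correlation, hill-climbing Bayesian, and network-outcome
    analyses. Includes a CT phantom generator and a synthetic cohort
    generator so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    grDevices,
    graphics,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet
Config/testthat/edition: 3
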