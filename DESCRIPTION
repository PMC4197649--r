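Package: stereomatch
Title: Cross-Matching Models of Stereo Correspondence in Random-Dot Stereograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for modelling binocular disparity detection in random-dot
    stereograms (RDSs). Implements window-based cross-correlation and its
    half-wave-rectified modification ("cross-matching"), a generalized form
    with rectification after spatial averaging, and the equivalent ON/OFF
    channel formulation. Provides an RDS generator with graded binocular
    anticorrelation and an embedded disparity plane, exact trinomial theory
    for the operators' expected values and distributions, Monte-Carlo
    variability surfaces, Gabor-based disparity-energy and threshold-energy
    detectors, and simulated two-alternative forced-choice near/far
    psychometric functions with opponent decoding and Gaussian decision
    noise.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    rlang,
    generics,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
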