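Package: cryopolish
Title: Statistical Movie Processing for Cryo-EM Single-Particle Refinement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-frame alignment of dose-fractionated cryo-EM particle
    movies under Gaussian orientational and translational priors inside a
    regularized-likelihood refinement loop. Includes a movie simulator with
    known ground-truth poses and beam-induced motion, a gold-standard
    (independent half-set) projection-matching refinement engine built on
    Fourier central-slice projection, running-average movie-frame alignment
    with priors centred on the whole-exposure alignment ("particle
    polishing"), tilt-pair validation of angular accuracy, and
    postprocessing: masked Fourier shell correlation, resolution at
    FSC = 0.143, MTF correction, Guinier B-factor estimation and
    sharpening, and the Rosenthal-Henderson particle-number extrapolation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
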