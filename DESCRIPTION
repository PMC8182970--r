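Package: vfbayes
Title: Bayesian Estimation of Vocal Fold Material Properties from
    Glottal Width Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward modelling and Bayesian calibration of a layered
    two-dimensional finite-element vocal fold vibrating against a
    hemilaryngeal contact plane.  The fold is driven by either a Bernoulli
    glottal flow model with a prescribed or estimated flow-separation ratio,
    or by a one-dimensional viscous collapsible-tube flow model with
    vena-contracta and pressure-recovery closures.  Material properties
    (layer elastic moduli, density, Kelvin-Voigt viscosity, medial
    compression) and subglottal pressure are estimated from length-averaged
    glottal width waveforms by importance sampling, and synthetic-twin
    studies quantify the sensitivity of the estimates to the choice of flow
    model and separation-ratio handling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    tools,
    pracma,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    withr,
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
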