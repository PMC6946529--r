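Package: starph
Title: Discrete Stochastic and Continuum Models of Single-Vesicle Acidification
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the acidification of single proteoliposomes by proton
    pumps at the level of discrete molecules. Provides an exact stochastic
    (Gillespie-type) jump-process engine and a matched continuum ODE engine
    for a reaction network comprising a proton pump, passive H+ and K+
    membrane leaks with membrane-potential-coupled rates, two lumenal
    buffers, and impermeant Donnan particles; the fluorescent-dye photon
    observable with Poisson shot noise and linear calibration; trace
    segmentation and Nelder-Mead parameter estimation of pump rate and
    membrane permeabilities from single-vesicle pH recordings; and
    fluctuation analysis (standard deviations, Fano factors, Poisson
    goodness of fit, closed-form noise scaling laws) of simulated and
    observed traces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
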