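Package: screenmst
Title: Feature-Specific Natural History and Interval-Cancer Modelling for
    Mammography Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Three-state Markov (disease-free, pre-clinical detectable
    phase, clinical phase) natural-history modelling of screen-detectable
    breast cancer stratified by mammographic feature.  Provides the exact
    likelihood of individual screening histories under imperfect,
    feature-specific test sensitivity; maximum-likelihood and random-walk
    Metropolis MCMC estimation of pre-clinical incidence, sensitivity-
    adjusted mean sojourn time and screening sensitivity; a closed-form and
    microsimulation engine for proportional interval-cancer incidence (the
    I/E ratio) as a function of inter-screening interval and sensitivity;
    and a reproducible synthetic cohort generator emulating trial-era and
    service-era mammography screening designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
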