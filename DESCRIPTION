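Package: tgfscreen
Title: Response-Type Screening for a TGF-beta/Smad Signaling Network Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates a two-compartment ordinary-differential-equation model
    of the core TGF-beta/Smad signaling network with an I-Smad-mediated
    negative feedback, and screens its kinetic parameter space by Monte-Carlo
    sampling. Each sampled parameter set is classified into one of six
    response phenotypes (unresponsive, sustained, transient, dampened- or
    sustained-oscillatory, undefined) from the time course of the nuclear
    R-Smad/Co-Smad complex. Downstream analyses cover switching of the
    response type under changed cellular protein concentrations,
    dose-response saturation fitting, and the fidelity of the pathway as a
    proportional read-out of time-varying ligand inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    tibble,
    dplyr,
    purrr,
    rlang,
    tidyr,
    ggplot2,
    yaml,
    xml2,
    readr,
    stats,
    utils,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
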