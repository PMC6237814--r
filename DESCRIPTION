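Package: rmthermo
Title: Thermodynamic Modeling of Transcription Regulation in the Kpn2I
    Restriction-Modification System
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative model of transcription regulation in the Kpn2I
    restriction-modification system: a Shea-Ackers statistical-weight model
    of the shared kpn2I.M/kpn2I.C regulatory region with an
    elongation-roadblock read-through term, estimation of the regulatory
    constants (f, g, alpha-tilde, beta) from transcript-ratio observables,
    deterministic ODE dynamics of rescaled transcript and protein amounts
    during system establishment in a naive host, in-silico perturbation
    experiments (controller-protein knockout, read-through sweeps), and a
    synthetic-data generator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
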