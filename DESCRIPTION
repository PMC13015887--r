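Package: patune
Title: Thermodynamic Simulation and Tuning of Programmable Nucleic Acid
    Amplification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A simulator and design toolkit for tag-primer PCR in which a
    5' energy-compensating tag progressively restores the amplification
    efficiency of a deliberately weakened primer.  Provides
    nearest-neighbor DNA hybridization thermodynamics (free energy,
    melting temperature, salt correction, two-state binding probability),
    a per-cycle kinetic PCR simulator with short-template/long-template
    bookkeeping, response-curve and dynamic-range analysis of efficiency
    versus binding free energy, a stacked-ensemble regression harness for
    predicting quantification cycle (Ct) values from primer features, and
    application simulators for sequencing read allocation (fusion
    detection limits) and tiered random access in DNA data storage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    ranger,
    xgboost,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
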