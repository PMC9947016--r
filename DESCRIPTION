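Package: cardiotd
Title: Cellular Toxicodynamic Modelling of Doxorubicin Cardiotoxicity and
    Dexrazoxane Cardioprotection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic cell-level toxicodynamic (TD) modelling of
    doxorubicin (DOX)-induced loss of cardiomyocyte viability and its
    attenuation by dexrazoxane (DEX). Implements exponential drug
    degradation in culture medium, an exponential-growth transit-
    compartment kill model with a Hill drug-drug interaction, pooled
    weighted least-squares parameter estimation with relative standard
    errors, seeded synthetic-data generators emulating the in vitro
    design, and an in vitro-in vivo translation layer with compartmental
    infusion pharmacokinetics, virtual populations with lognormal
    inter-individual variability, and AUEC-based optimisation of
    DEX:DOX dose ratios and dose-fractionation schedules.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse,
    ggplot2
Config/testthat/edition: 3
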