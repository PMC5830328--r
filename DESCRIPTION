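Package: rtimmune
Title: Tumor-Immune Dynamics Under Radiotherapy and PD-(L)1 Blockade
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A quantitative systems pharmacology simulator of the cancer
    immunity cycle in syngeneic CT26 tumors. Couples logistic tumor growth,
    radiation-induced cell kill and DNA double-strand-break dynamics,
    dendritic-cell maturation, systemic antigen presentation, effector
    T-cell priming and killing, and two immuno-suppressive axes (PD-L1 and
    cellular suppression) in a single ODE system. Includes one-compartment
    intraperitoneal antibody pharmacokinetics with receptor occupancy, a
    lognormal inter-animal-variability layer on T-cell infiltration, a
    synthetic tumor-volume study generator, mixed-effects refitting of the
    population parameters, and a virtual-trial engine for dose-schedule and
    sequencing optimization of combined radiation and checkpoint blockade.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    yaml,
    pracma,
    tibble,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
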