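Package: nilrad
Title: Population Dynamics of TKI Resistance Under Combined Nilotinib and
    Low-Dose Radiation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic compartment model of Philadelphia-chromosome
    positive acute lymphoblastic leukemia cell populations under tyrosine
    kinase inhibitor (Nilotinib) therapy and low-dose ionizing radiation.
    Provides linear drug-by-radiation dose-response rate functions,
    linear-quadratic instantaneous radiation kill, piecewise ODE simulation
    of sensitive/resistant/dead compartments under arbitrary fractionated
    treatment schedules, staged least-squares calibration to cell-viability
    time series, synthetic viability data generation, and constrained
    optimization of radiation fractionation and drug-titration schedules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    lhs,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
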