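Package: dermapkpd
Title: Dermal PBPK Simulation of Topical Gel Release and Skin Permeation
    with Population Pharmacodynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic compartmental modeling of dermal drug delivery from
    semi-solid (gel) formulations. Implements a general mass-transport ODE
    engine (flux J = P*A*(C1 - C2/Kp) with interface lag times), in vitro
    release testing (IVRT) and in vitro permeation testing (IVPT) Franz
    diffusion cell models with a two-phase gel donor, stepwise calibration
    of release and skin partition parameters with a six-metric goodness-of-fit
    battery (RMSE, MAPE, AFE, bias, R-squared, Pearson r), Morris
    elementary-effects sensitivity screening, and a population sigmoid-Emax
    pharmacodynamic stage (proportional residual error, log-normal
    between-subject variability, empirical Bayes estimates, information
    criteria, visual predictive checks, IWRES/NPDE diagnostics). A seeded
    synthetic-data generator emulates the replicate structure, below-LOQ
    censoring and sparse clinical sampling of the experimental designs so
    that the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
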