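Package: dosedesign
Title: Optimal-Control Design of Personalized Drug Dosing Schedules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Patient-specific pharmacokinetic/pharmacodynamic (PK/PD)
    modelling and open-loop optimal-control design of discrete oral dosing
    schedules, with imatinib in chronic myeloid leukemia (CML) as the worked
    case. Provides covariate-based one-compartment oral-absorption PK models,
    biphasic log-linear fitting of longitudinal BCR-ABL tumor-burden series,
    estimation of patient-specific Emax pharmacodynamics from the fitted
    cancer-stem-cell decay rate, and a chopped-random-Fourier-basis schedule
    optimizer with target-concentration and burden/exposure cost functionals,
    plus robustness analyses against intra-patient variability and systematic
    parameter errors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    withr
Config/testthat/edition: 3
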