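Package: coroflow
Title: Coronary Flow Velocity Reserve Analysis with the CCFVR Companion Metric
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing transthoracic Doppler coronary flow
    measurements in heart-transplant cohorts. Computes coronary flow
    velocity reserve (CFVR), its velocity-domain companion metric CCFVR
    (the Euclidean norm of the resting/hyperemic diastolic peak velocity
    pair), microvascular resistance indices (BMR, HMR, ARI) and the
    rate-pressure-normalised reserve. Classifies subjects into four
    microvascular endotypes from CFVR and hyperemic velocity, into four
    variant endotypes from CFVR and CCFVR, and cross-tabulates the
    reclassification of cardiovascular deaths between the two schemes.
    Provides a prognostic layer (Kaplan-Meier, log-rank, Cox proportional
    hazards with univariable screening, Harrell's C, likelihood-ratio
    tests, continuous net reclassification improvement), measurement
    agreement statistics (regression agreement, Bland-Altman limits,
    intraclass correlation) and a calibrated synthetic cohort generator
    so the full pipeline runs without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
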