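Package: ringdose
Title: Sub-Organ Ring Decomposition and Neural-Network Dose Prediction for
    Needle-Insertion Cervical-Cancer Brachytherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Knowledge-based organ-at-risk (OAR) dose prediction and plan
    quality assurance for high-dose-rate needle-insertion brachytherapy of
    cervical cancer. Each OAR (bladder, rectum, sigmoid colon) is decomposed
    into concentric 0.3 cm exterior distance rings around the high-risk
    clinical target volume (HR-CTV); the normalized sub-organ volumes,
    together with the HR-CTV volume, feed a one-hidden-layer feed-forward
    network trained with a Levenberg-Marquardt optimizer under a
    multi-restart best-validation protocol to predict the scale-free
    D2cm3/D90 dose ratio per OAR. Includes dose-volume-histogram metrics
    (D2cm3, D90), EQD2 conversion and constraint auditing, cohort correlation
    reports, fit evaluation (regression R, MSE, absolute-difference
    statistics, paired t tests), a QA threshold gate, a synthetic pelvic
    phantom cohort generator with an inverse-square dwell dose kernel, and
    NIfTI/CSV readers and writers tying the stages into a reproducible
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
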