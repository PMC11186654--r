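Package: iustherm
Title: Acoustic-Biothermal Simulation and Treatment Planning for
    Catheter-Based Interstitial Ultrasound Ablation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward simulation engine and planning tools for thermal
    ablation of soft tissue (primarily prostate) with catheter-based
    interstitial ultrasound applicators.  Computes acoustic power
    deposition of sectored tubular-transducer arrays, solves the Pennes
    bioheat transfer equation with an explicit finite-difference
    time-domain scheme including catheter/urethral convective cooling and
    thermal-dose-dependent perfusion shutdown, accumulates CEM43 thermal
    dose, extracts ablation-zone dimensions and volumes, and supports
    temperature-feedback power control, parameter-sweep lookup tables,
    NRRD volume export, STL voxelization and synthetic pelvic anatomy.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
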