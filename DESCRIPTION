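Package: tcmbmd
Title: Opportunistic CT Bone Densitometry with a Two-Compartment Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies volumetric bone mineral density (vBMD) of lumbar
    vertebrae from routine abdominal CT by modelling trabecular bone as a
    two-compartment mixture of cortical-bone-equivalent mineral (K2HPO4
    solution) and marrow-equivalent water. Provides a polyenergetic
    simulator of the ten-solution K2HPO4 calibration phantom used to
    validate the energy independence of the method, elliptical
    region-of-interest measurement on CT volumes (NIfTI), DXA T-score
    classification, ROC/Youden derivation of vBMD diagnostic thresholds
    for osteoporosis and osteopenia screening, and a synthetic cohort
    generator so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pracma,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
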