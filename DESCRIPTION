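Package: cardiomict
Title: Quantification of Murine Myocardial Infarction from Gated
    Contrast-Enhanced Micro-CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and quantification pipeline for delayed-contrast-
    enhanced, prospectively gated cardiac micro-CT in the mouse. Generates
    digital heart phantoms with known ejection fraction, infarct geometry and
    iodine washout kinetics; simulates dual cardiorespiratory gating of a
    step-and-shoot scanner; segments the left-ventricular blood pool,
    myocardium and infarct from Hounsfield-unit volumes by threshold-
    constrained seeded region growing; quantifies infarct fraction from
    TTC-stained slice photographs by color segmentation; and compares the
    two modalities with correlation and t-test statistics, including
    outlier-excluded agreement reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    png,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
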