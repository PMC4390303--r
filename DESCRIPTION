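Package: rifcalib
Title: Internal Blood Dosimetry and Calibration of the gamma-H2AX/53BP1
    Focus Assay
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for calibrating the gamma-H2AX/53BP1 DNA double-strand
    break focus assay against absorbed dose to blood after internal
    irradiation with the beta emitters I-131 and Lu-177.  Includes a Monte
    Carlo model of a radionuclide-spiked blood vial yielding S-values
    (absorbed dose rate per disintegration in 1 ml of blood), decay-
    integrated absorbed-dose computation and activity planning, Poisson
    foci-counting statistics with background subtraction, per-dataset and
    pooled linear dose-response calibration with confidence bands and
    inverse dose estimation, and a synthetic-study generator for
    parameter-recovery and coverage simulations.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
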