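Package: pcdquant
Title: Phantom-Based Calibration for Material Decomposition in
    Photon-Counting CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Calibrates and corrects two-material decomposition for
    photon-counting detector CT (PCD-CT). From phantom ROI measurements
    the package estimates the base-material CT-number mismatch
    (delta_base), the dual-energy ratio (DER) and the concentration
    scaling factor (alpha) by linear fits, aggregates them per tube
    voltage into a "mean method", and converts paired low/high-energy CT
    numbers into corrected iodine or iron concentrations (mg/mL). A
    synthetic spectral abdomen phantom generator provides paired
    low/high-energy images with known ground truth so the whole pipeline
    is testable without scanner data. Includes circular-ROI extraction
    from NIfTI or raw-array image pairs and a command-line workflow
    (simulate, calibrate, aggregate, quantify).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    RNifti,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
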