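Package: RamanCohort
Title: Preprocessing and Cohort Analysis of Fiber-Probe Tissue Raman Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for intraoperative fiber-probe Raman spectroscopy of tissue:
    dark-frame correction, cosmic-spike removal, relative intensity calibration
    against a certified fluorescence standard, asymmetric least squares (ALS)
    background correction, correlation-based spectrum quality filtering, area
    normalization, cohort mean/SD and tumor-minus-healthy difference spectra,
    peak detection with molecular band assignment, per-band effect sizes, and
    two-sample sample-size planning. Includes a seeded forward simulator of
    fiber-probe tissue Raman measurement sites with full ground-truth manifests
    so every processing stage can be validated without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
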