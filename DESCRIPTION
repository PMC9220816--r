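Package: epedetect
Title: Rule-Based Detection of Prostate Cancer Extraprostatic Extension
    from Probability Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing pipeline that converts voxelwise prostate-cancer
    probability maps into localized predictions of extraprostatic extension
    (EPE). Lesion candidates are extracted as 26-connected components of a
    thresholded, capsule-dilated probability volume and filtered by two
    clinical rules: the candidate must cross the prostate capsule, and its
    tumor-capsule contact line length (TCL) must exceed a threshold in mm.
    Includes MRI intensity standardization (histogram-landmark alignment and
    region Z-scoring), sextant-level and patient-level evaluation with ROC
    construction over the probability-threshold grid, a TCL threshold grid
    search, and a seeded geometric phantom generator that emulates upstream
    cancer-detection model output for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    EBImage,
    igraph,
    jsonlite,
    grDevices,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
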