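Package: oralaf
Title: Multispectral Autofluorescence Endoscopy Analysis of Oral Lesions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis pipeline for discriminating cancerous and
    pre-cancerous from benign oral lesions using multispectral autofluorescence
    endoscopic imaging. Provides decay-cube preprocessing (offset subtraction,
    saturation masking, spatial smoothing, SNR masking), per-pixel spectral
    intensity features for the collagen, NADH and FAD emission bands, an
    L1-regularized linear support vector machine with embedded feature
    selection, pixel-level posterior probability maps aggregated to image-level
    scores, constrained-ROC decision thresholding, and leave-one-patient-out
    cross-validation. Includes a synthetic cohort simulator of paired
    lesion/healthy fluorescence decay image cubes for testing the pipeline
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
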