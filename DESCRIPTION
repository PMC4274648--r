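Package: thyroCT
Title: Rule-Based CT Scoring and Diagnostic Accuracy Evaluation for Diffuse Thyroid Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a five-feature computed-tomography scoring system for
    incidentally detected diffuse thyroid disease (low parenchymal attenuation,
    inhomogeneous attenuation, increased glandular size, lobulated margin and
    inhomogeneous enhancement, counted against a "k or more" threshold),
    together with the statistical machinery needed to evaluate it: confusion
    counts, sensitivity/specificity/predictive values/accuracy, two-point ROC
    AUC with Hanley-McNeil confidence intervals, HU cut-off selection,
    chi-square feature comparison and univariate logistic fits. Ships a seeded
    synthetic cohort generator calibrated to published per-class Hounsfield
    unit distributions and feature frequencies, deterministic 209-patient
    reference fixtures that reproduce published confusion counts, and a
    synthetic neck-CT phantom generator with ground-truth lobe geometry on
    which the ROI, size, margin and pattern measurements are validated.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    withr,
    RNifti,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
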