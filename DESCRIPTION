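Package: blsvm
Title: Broad Learning SVM Ensembles for Multivoxel MRS Metabolite Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classification of neuropsychiatric systemic lupus erythematosus
    (NPSLE) from multivoxel proton magnetic resonance spectroscopy (1H-MRS)
    metabolite panels with a broad learning system of support vector
    machines (BL-SVM): layers of SVM nodes, trained layer-wise on bootstrap
    resamples, whose tanh-squashed decision values augment the input of
    every subsequent layer.  Includes Mann-Whitney U feature screening with
    per-feature ROC AUC, SVM-based recursive feature elimination with a
    cross-validated panel-size curve, repeated stratified k-fold evaluation
    (ROC/AUC, sensitivity, specificity), a packaged transcription of the
    published NPSLE-vs-control group statistics, and a class-conditional
    Gaussian cohort generator that emulates the study design (23 patients,
    16 controls, 117 region-by-metabolite features, missing-at-random
    dropouts) so the full pipeline is testable without the withheld
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
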