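Package: casefinder
Title: High-Sensitivity Case Identification from Free-Text Medical Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building high-sensitivity automated case-identification
    systems from free-text electronic medical records. Implements a
    keyword-driven assertion filter for negated, speculative, and alternative
    statements, chi-square-screened bag-of-words featurization, training-set
    construction with set expansion (implicit negative entries), modified
    random under- and over-sampling of the negative class, the MetaCost
    cost-sensitive meta-learning wrapper with conditional-risk relabeling, a
    chi-square decision-tree learner (MyC), subject-level cross-validation
    with patient-level sensitivity and specificity, an error taxonomy for
    missed cases, and a synthetic EMR corpus generator with a ground-truth
    sidecar for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    rpart,
    e1071,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
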