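Package: tugait
Title: Subtask Segmentation and Gait Feature Analysis for the Timed Up and Go Test
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for Timed Up and Go (TUG) assessments recorded as
    25-joint skeletal time series from a frontal depth camera. Provides a
    documented on-disk recording format, a synthetic TUG recording generator
    with ground-truth annotations, zero-phase Butterworth preprocessing with
    automated quality screening, detection of the five TUG subtasks
    (sit-to-stand, walk out, turning, walk back, stand-to-sit), extraction of
    a 61-feature spatiotemporal gait and balance profile, covariate-adjusted
    (ANCOVA) feature selection with normality-gated group tests and
    correlation pruning, and SVM-based two-group discrimination under
    five-fold and leave-one-subject-out cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    pracma,
    signal,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0), optparse, withr, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
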