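Package: vcglvh
Title: Electrovectorcardiographic Detection of Left Ventricular Hypertrophy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting echocardiographic left ventricular hypertrophy
    (Echo-LVH) from 12-lead median-beat electrocardiograms. Synthesizes
    vectorcardiographic X/Y/Z leads by four linear transform methods (inverse
    Dower, Kors regression, and two least-squares variants) with optional
    Fourier smoothing, segments P/QRS/T loops and extracts global and
    per-decile loop geometry features, computes 23 classical ECG voltage
    criteria with sex-specific cut-offs, prunes features by cross-validated
    lasso, induces interpretable gain-ratio decision trees (C4.5/C5.0 lineage)
    with misclassification-cost weighting, and provides the full evaluation
    suite (exact confusion-matrix statistics, DeLong comparison of correlated
    ROC curves, McNemar tests with Bonferroni correction, k-fold cross
    validation, stratified correct-classification tables and two-proportion
    power). A synthetic median-beat and cohort generator with analytic ground
    truth makes the whole pipeline testable end to end.
License: MIT
Encoding: UTF-8
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
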