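Package: weanpower
Title: Mechanical-Power Indices and Diagnostic Evaluation for Weaning Readiness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes ventilator-derived candidate predictors of spontaneous
    breathing trial (SBT) failure in prolonged mechanically ventilated
    patients: dynamic driving pressure, dynamic lung-thorax compliance,
    simplified mechanical power under pressure-controlled ventilation, its
    normalizations to predicted body weight and to compliance, the ventilatory
    ratio, and the Power index of the respiratory system (compliance-normalized
    mechanical power rescaled to isocapnic conditions at a 45 mmHg PaCO2
    target). Provides the full diagnostic-evaluation pipeline used to assess
    such indices: confusion-matrix metric batteries with exact binomial
    confidence intervals, ROC curves with DeLong AUROC inference, Youden
    threshold selection, stratified repeated k-fold cross-validation with
    training-fold threshold learning, group comparisons, binary logistic
    regression with forward selection, Hosmer-Lemeshow calibration and
    Nagelkerke R-squared, and a seedable synthetic two-group cohort generator
    for testing the pipeline without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    nortest,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
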