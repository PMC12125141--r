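Package: pshrisk
Title: Transients Between Autonomic Activity and Cerebral Hemodynamics for
    Early PSH Risk Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the risk of paroxysmal sympathetic hyperactivity (PSH)
    after traumatic brain injury from transient changes in the correlation
    between autonomic-nervous-system metrics (heart rate, arterial blood
    pressure, baroreflex sensitivity) and cerebral hemodynamics
    (intracranial pressure, pressure reactivity index). Provides a
    synthetic multimodal-neuromonitoring cohort generator, waveform-level
    estimators for heart rate, baroreflex sensitivity and the pressure
    reactivity index, quality control and gap interpolation for 60-s trend
    data, rolling-window Pearson correlation with mean, standard deviation
    and zero-crossing-rate variability metrics, nested clinical /
    neuromonitoring / transient feature sets, an L2-penalised logistic
    risk model evaluated by stratified five-fold cross-validation over a
    regularisation grid, and coefficient- and attribution-based feature
    importance with a temporal significance profile.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
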