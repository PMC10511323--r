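Package: BanditPhotometry
Title: Striatal Dopamine and Acetylcholine Dynamics in a Two-Armed Bandit Task
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis toolkit for fibre-photometry recordings of
    striatal dopamine (DA) and acetylcholine (Ach) during a probabilistic
    two-armed bandit task. Provides a task and agent simulator with a
    recursively formulated logistic regression (RFLR) choice model and its
    maximum-likelihood fit, a synthetic photometry generator with per-event
    kernels, history-dependent amplitudes and a lagged negative DA-to-Ach
    coupling, lock-in (quadrature) demodulation of frequency-multiplexed
    carriers, dF/F0 and z-score preprocessing with event-aligned trial
    tensors, per-trial metrics with paired group tests and regularized linear
    discriminant classification, time-shifted design-matrix encoding GLMs
    (OLS, ridge, lasso, elastic net) with grouped cross-validation and
    leave-one-feature-out analysis, and trial-aligned covariance analyses
    including lagged cross-covariance, noise correlations, the
    two-dimensional covariance function K(t1,t2) with off-diagonal summaries,
    and permutation null controls.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    glmnet,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
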