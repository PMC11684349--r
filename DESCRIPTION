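Package: fedstress
Title: Privacy-Preserving Multitask Federated Learning for Wearable Stress
    Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and evaluation framework for balancing utility and
    privacy when recognising stress from wearable physiological signals
    (electrodermal activity, blood volume pulse, acceleration, skin
    temperature, electrocardiogram). Implements a multitask 1D convolutional
    network with a shared trunk, a binary stress head and a subject-identity
    branch; federated averaging with a proximal local objective; and
    differential-privacy hardening via update clipping and Laplace/Gaussian
    noise injected into a configurable subset of layers (full model, shared
    trunk, or task-specific branches). Ships a seeded synthetic multimodal
    signal generator with controllable identity separability and stress
    effect size, a sliding-window feature extractor (moments, amplitude
    differences, band powers, histogram entropy), stratified k-fold
    evaluation, modality ablations and privacy-utility sweep experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pROC,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
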