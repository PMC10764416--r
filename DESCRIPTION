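Package: gaitfog
Title: Freezing-of-Gait Detection from Wearable Inertial Sensor Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting freezing of gait (FOG) in
    people with Parkinson's disease from multichannel accelerometer
    recordings. Covers the full analysis chain: artifact rejection and
    zero-phase Butterworth band-pass conditioning of raw inertial signals,
    standardization to 60 Hz, two-second epoching with 75% overlap and
    fraction-based FOG labeling, three time-series classifier families (a
    compact convolutional network, an InceptionTime ensemble, and the
    MiniRocket random-kernel transform with proportion-of-positive-values
    pooling and a logistic head), subject-grouped cross-validation,
    ROC/AUC model selection, operating-point selection by the geometric
    mean of sensitivity and specificity, and a sensor-placement ablation
    over five wearing configurations. A seeded synthetic gait cohort
    generator with trembling and akinetic freezing phenotypes provides
    reproducible data for development and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
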