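Package: balonn
Title: Bayesian Logic-Operator Neural Networks for Uncertainty-Aware Clinical Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and trains Bayesian logic-operator neural networks
    (BaLONNs): small feed-forward networks whose hidden layers are frozen
    perceptrons implementing continuous (Lukasiewicz) logic gates through
    squashing activations, and whose trainable layers carry mean-field
    Gaussian weight posteriors fitted by variational inference. Includes a
    synthetic electronic-health-record cohort generator for heart-failure
    style data, SMOTE class balancing, tolerance-based uncertainty-aware
    validation statistics (sampled predictive distances, micro-averaged
    precision, traffic-light reports) and prior/posterior scale sensitivity
    sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
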