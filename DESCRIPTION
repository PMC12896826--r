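Package: herdprune
Title: Cattle Behavior Recognition with a 1-D Residual Network and
    Graph-Based Reinforcement-Learning Channel Pruning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for recognizing cattle behaviors (grazing, lying,
    standing, walking) from collar-mounted inertial and GPS sensors, and
    for compressing the classifier for edge deployment. Provides a
    synthetic herd-sensor generator with the full preprocessing chain
    (haversine GPS displacement, 10-feature frame assembly, SMOTE class
    balancing, train-set standardization, stratified splitting); a
    single-frame 1-D residual convolutional classifier (S-ResNet) with
    training, fine-tuning and multiply-accumulate accounting; a
    structured channel-pruning environment with residual coupling groups
    and FLOPs budgeting; a graph-convolutional actor-critic agent trained
    with twin-delayed deep deterministic policy gradients (TD3) that
    searches layer-wise channel retention rates; and evaluation utilities
    (confusion matrices, per-class sensitivity and precision, Cohen's
    kappa, repeated-experiment aggregation) with a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    e1071,
    geosphere,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
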