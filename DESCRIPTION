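Package: ganbalance
Title: Class Balancing for Small-Sample Omics Data with Penalized Wasserstein GANs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Synthetic oversampling for high-dimensional, small-sample omics
    matrices using a Wasserstein generative adversarial network with gradient
    penalty, transfer-learning pre-training on an unlabeled external dataset,
    progressive network growing, and automated training-control heuristics
    (loss-trace truncation, instability and speed scores, learning-rate and
    knee-point epoch selection). Includes per-class GAN balancing and expanded
    generation, SMOTE and random-oversampling baselines, skewness-gated
    per-feature scaling (Yeo-Johnson or robust), LASSO/elastic-net stability
    feature selection, a two-cluster microarray simulator, and a validation
    protocol scoring repeated balanced training runs by AUROC with Welch and
    Benjamini-Hochberg comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    minpack.lm,
    pROC,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
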