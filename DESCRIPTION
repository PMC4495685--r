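Package: dtal
Title: Active Learning for Drug-Target Interaction Prediction with a
    Simulation-Calibrated Stopping Rule
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kernelized Bayesian matrix factorization (KBMF) for binary
    drug-target interaction matrices, driven by uncertainty-sampling active
    learning, together with a simulation-calibrated lasso regression model
    that predicts the learner's current accuracy and supplies a stopping
    rule for experimentation. Includes a synthetic-data generator for
    interaction matrices with prescribed uniqueness and responsiveness,
    'perfect' Gaussian kernels with controlled corruption, trajectory
    feature extraction, exceedance calibration, and classical stopping
    criteria (overall uncertainty, minimum expected error) for comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
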