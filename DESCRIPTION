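Package: bfindep
Title: Bayesian Test of Independence for Classifier Confusion Matrices
Version: 0.1.0
Authors@R:
    person("bfindep", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Evaluates binary classification results as a Bayesian test of
    statistical independence between predicted and true class labels. Given a
    2x2 confusion matrix with fixed row margins (one margin fixed), the package
    computes the intrinsic-prior Bayes factor of dependence versus independence
    in closed form in log space, minimized conservatively over the
    prior-concentration hyperparameters, and interprets it on the standard
    evidence scale. The usual evaluation metrics (prediction accuracy, MCC,
    F1, Cohen's kappa, Youden's J) are provided for comparison, together with
    an independent beta-binomial oracle for auditing the closed form, a
    row-binomial simulator for synthetic confusion matrices, and command-line
    entry points.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
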