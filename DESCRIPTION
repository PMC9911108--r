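Package: tlpsvm
Title: Nonconvex-Penalized Smooth-Hinge Support Vector Models for Binary
    Clinical Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Variable selection and model building for binary clinical
    outcomes measured on small cohorts with many candidate variables.
    Implements a smooth (softplus) approximation of the hinge loss with
    nonconvex penalties (truncated lasso, SCAD, MCP) solved by a
    difference-of-convex algorithm; a model-free nonparametric screening
    stage for nonlinear marginal and pairwise joint effects with
    permutation p-values; a stepwise forward builder for mixed
    linear/B-spline support vector models evaluated by leave-one-out
    cross-validation; a permutation test for model overfitting; and a
    seeded synthetic-cohort generator with known ground truth so every
    stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    pROC,
    pheatmap,
    optparse
Config/testthat/edition: 3
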