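Package: twostepr
Title: Simulation and Analysis of the Rat Two-Step Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for simulating and analysing the rat two-step
    decision task. Provides a generative model of the task environment
    (block-reversal reward schedules with probabilistic
    choice-to-outcome transitions), a mixture-of-agents cognitive model
    (model-based planning, novelty preference, perseveration and bias)
    with maximum-a-posteriori fitting, trial-history logistic
    regressions and the planning/model-free behavioral indices,
    Poisson-GLM spike-count encoding analyses based on coefficients of
    partial determination with circular-permutation inference, and
    synthetic optogenetic-inactivation cohorts that dissociate the role
    of value representations in learning from their role in choice.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
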