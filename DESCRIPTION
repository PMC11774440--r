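Package: gateflow
Title: Learning Dynamics of Gated Linear Networks on Blocked Task Curricula
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses the joint gradient-flow dynamics of linear
    teacher-student networks whose pathways are modulated by fast, bounded,
    nonnegative gating variables. Tasks defined by random orthogonal teachers
    are presented in a blocked curriculum; the package integrates the coupled
    weight/gate dynamics, reduces them exactly to low-dimensional coordinates
    in the singular-value space of the teachers, and quantifies specialization,
    catastrophic forgetting, task-switching speed and compositional
    generalization. Includes an exact closed-form solution for symmetric
    specialized adaptation, a two-layer fully-connected linear variant with
    emergent gating, and scripted experiment suites (regime comparison,
    task/subtask composition, phase diagrams, switch-speed trends).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
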