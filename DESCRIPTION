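Package: pbac
Title: Closed-Loop Gaze-Contingent Interception Experiments and
    Hierarchical Bayesian Learning Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale toolkit for prediction-based attention computing
    (PbAC): a virtual-interception experiment simulator whose trial outcomes
    are driven by (synthetic) gaze, together with the full offline analysis
    stack. Includes court geometry and ballistic ball flight, three trial
    allocation schemes (probability-controlled, gaze-contingent, matched
    order), closed-loop generative agents with belief-driven gaze and
    surprise-scaled pupil responses, gaze and pupillometry signal pipelines,
    binary Rescorla-Wagner, Sutton K1 and 2/3/4-level Hierarchical Gaussian
    Filter learning models with observing-the-observer MAP fitting and
    Laplace log-model evidence, random-effects Bayesian model selection with
    protected exceedance probabilities, and condition-by-expectedness
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    jsonlite,
    readr,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
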