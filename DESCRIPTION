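Package: sirel
Title: Single-Item Reliability Estimation and Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the reliability of a single-item assessment from one
    administration of the item together with a multi-item scale of the same
    construct. Implements five estimators: correction for attenuation,
    factor-analysis communality, the double-monotonicity joint cumulative
    probability estimator, an adaptation of Guttman's lambda-6, and a latent
    class model estimator. Also provides a graded-response-model simulator for
    polytomous Likert data and a Monte Carlo study harness that compares the
    estimators on bias, interquartile range, outlier rate and root mean square
    error, selects the most precise method per condition via Kruskal-Wallis
    tests with Dunn post-hoc comparisons, and regresses bias on the design
    factors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
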