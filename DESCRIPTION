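Package: threshsa
Title: Probabilistic Parameter Threshold Analysis by Pairwise Stochastic
    Approximation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-theoretic probabilistic sensitivity analysis for
    decision-making under uncertainty, aimed at health economic evaluation.
    Locates probabilistic parameter thresholds - the values of a single
    uncertain model input at which the conditionally optimal decision option
    switches - with a pairwise Robbins-Monro stochastic approximation
    root-finder with Polyak-Ruppert averaging, and post-processes candidate
    thresholds with one-sided hypothesis tests. Computes the decision
    switching probability (DSP) sensitivity measure from closed-form marginal
    distributions, the expected value of (partial) perfect information (EVPI,
    EVPPI) by paired and nested Monte Carlo, and a nested Monte Carlo
    threshold baseline. Ships a fully specified synthetic three-treatment
    cost-effectiveness model on the net monetary benefit scale, with
    correlated cost, odds-ratio and side-effect-probability inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
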