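Package: resdec
Title: Local Reservoir Models of Choice-Based Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying choice-based learning (CBL), the tendency of
    a decision maker to repeat an earlier choice, through the lens of a
    "local reservoir": a finite hidden environment of single-occupancy
    energy levels that absorbs the energy dissipated by each decision.
    Provides a discrete-cycle stochastic simulator of the reservoir with a
    configurable recovery lifetime, its exact continuous-time Markov chain
    counterpart (state enumeration, rate-matrix construction, steady state,
    and first-passage decision-transition probabilities), a single-photon
    decision-maker simulator in which a polarizing beam splitter and a
    waveplate of finite angular resolution realize the same dynamics, and a
    scorer for paired-preference behavioral experiments with reservoir-size
    estimation from observed decision consistency.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
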