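Package: grouprecip
Title: Evolution of Direct Reciprocity in Group-Structured Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the evolution of memory-1 strategies of direct
    reciprocity (repeated donation game with implementation errors) in
    populations subdivided into groups. Provides exact repeated-game payoffs
    and cooperation levels via Markov-chain and determinant methods, exact
    error-free limits by rational arithmetic, intra-group and population-wide
    fixation probabilities and times under a pairwise-comparison (Fermi)
    process, Monte Carlo simulation of the rare-mutation resident-mutant
    chain, and a replicator-mutator differential equation plus group-level
    Monte Carlo for the regime where mutation and between-group imitation
    occur on comparable time scales.
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
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
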