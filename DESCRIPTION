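Package: coopmove
Title: Evolution of Cooperation Under Coordinated Movement on Complete Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the evolution of cooperation in finite structured
    populations whose members move in a coordinated (row-dependent) way.
    Implements faithful movement mechanisms on the complete territorial-raider
    graph (independent movement, follow-the-majority herding, a Polya-urn
    interpolation, and a wheel-and-base dispersal mechanism), exact and
    Monte-Carlo group-formation distributions, multiplayer Public Goods and
    Hawk-Dove games, birth-death fixation-probability analytics under BDB and
    BDD dynamics (closed forms, a full Markov-chain solver, and weak-selection
    approximations), and a fast agent-based simulator of the full stochastic
    evolutionary process.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
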