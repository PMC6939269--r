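Package: cultlink
Title: Agent-Based Simulation of Linked Cultural Trait Transmission
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An agent-based simulator of cultural change in a well-mixed
    population where discrete cultural traits can become linked within
    individuals and are then transmitted together as a package. Supports
    unbiased, pay-off-biased and conformist-biased partner choice, link
    formation and breakage, innovation, and a fixed-package-size control
    mode. Includes the accompanying statistics layer: multi-variant pairwise
    difference (heterogeneity) with Wright-Fisher expectations, link and
    package-size summaries, distribution-overlap (equifinality) analysis,
    and cultural selective-sweep and hitchhiking metrics, together with
    exact small-population oracles for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
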