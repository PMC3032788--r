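Package: modmet
Title: Modular Artificial Chemistries and the Robustness of Metabolic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates atom-explicit, mass-conserving chemical reaction systems
    whose substance-graph modularity is tunable, simulates their mass-action
    kinetics to equilibrium with explicit Euler integration, applies four
    classes of mass-conserving perturbations (metabolic or genetic, local or
    global), and quantifies system-wide and focal robustness together with
    relaxation times as functions of network modularity. Includes a greedy
    agglomerative modularity maximizer with an exact brute-force oracle,
    ensemble sweep machinery over the modularity control parameter, and
    tidy/ggplot2 accessors for the resulting tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
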