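Package: mlspgg
Title: Multilevel Selection Dynamics of Conditional Cooperation in Public Goods Games
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Agent-based simulation of the evolution of conditional cooperation
    under multilevel selection. Individuals play continuous-contribution public
    goods games inside groups using one of 27 conditional strategies encoded as
    piecewise linear response functions; groups engage in probabilistic
    conflicts won with odds increasing in the contribution difference; strategy
    transmission is payoff-proportional within groups, with mutation and
    migration. The package provides the strategy encoding, the within-group
    equilibrium computation (iterated belief/response dynamics with limit-cycle
    averaging), the generational engine, Price-equation selection
    decompositions and variance-based selection-strength proxies, cooperative
    epoch statistics, and ready-made experiments (baseline dynamics, initial
    condition robustness, parameter sweeps, unconditional-strategy control).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
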