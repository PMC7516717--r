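Package: quoterflow
Title: Quoter-Model Simulation and Information-Flow Estimation on Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the quoter model, in which nodes of a social network
    grow timestamped text streams either by sampling new words from a Zipf
    vocabulary or by quoting segments of their neighbours' past text, and
    quantifies the resulting social information flow with nonparametric
    Lempel-Ziv match-length estimators of entropy rate and cross-entropy,
    together with Fano-bound predictability. Includes the network ensembles
    used to probe how structure shapes flow (Erdos-Renyi, Barabasi-Albert,
    Watts-Strogatz, dichotomous configuration-model and two-block stochastic
    block model graphs, plus degree-preserving x-swap randomization),
    event-driven SIR and threshold-SIR contagion baselines, and scenario
    runners for density, degree-heterogeneity, clustering, community and
    vocabulary-heterogeneity experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
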