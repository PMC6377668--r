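Package: heidercoop
Title: Reputation Heuristics, Cooperation and Group Polarization in
    Agent-Based Simulations
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Agent-based simulator of cooperation through signed reputation
    networks. Agents are randomly matched in Prisoner's Dilemma encounters
    and decide to cooperate or defect by aggregating gossip about the
    partner, weighting each third-party opinion by their own relationship
    with the opinion holder (Heider's structural-balance heuristics such as
    "a friend of a friend is a friend"). The package implements the signed
    reputation matrix, five agent strategies, the logistic decision
    function, relationship updating with memory constraints, and a
    frequency-dependent Moran process with exponential fitness and random
    mutation. A measurement layer provides mutual-positive network
    construction, Louvain community counting (network polarization),
    cooperation statistics, exponential-decay regressions, majority-state
    Markov chain estimation, fission-fusion cycle counting and the Rapoport
    cooperation index, plus preset experiments and seeded parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
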