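Package: shelterflow
Title: Discrete-Event Simulation of Homelessness Response Systems
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-event queueing simulation of the flow of people through a
    homelessness response system: Poisson arrivals with time-varying yearly
    rates, emergency shelter with priority admission and blocking (occupants
    cannot leave shelter until downstream housing is available), multiple
    housing pathways with triangular, uniform, or fixed occupancy-time
    distributions, time-varying capacity schedules ("investment policies"),
    and probabilistic returns to homelessness. Ships an aggregate
    single-pathway model and an eight-pathway detailed model for a large
    urban county, tools for building and scaling capacity-investment
    policies, replication statistics and unmet-need summaries, and
    closed-form queueing oracles (Erlang-C, Little's law, triangular CDF)
    for validating the engine.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
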