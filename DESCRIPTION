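Package: reacgraph
Title: Topology of Directed Reaction-Centric Metabolic Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts genome-scale metabolic models (SBML or plain reaction
    tables) into directed reaction-centric graphs, with currency-metabolite
    and transport/exchange filtering. Computes directed centrality metrics
    (clustering coefficient, betweenness, a direction-aware bridging
    coefficient and bridging centrality), cascade sets and cascade numbers
    that quantify how far an input-starvation failure propagates downstream
    of a removed reaction, degree distributions with power-law fits, directed
    modularity with degree-preserving randomization null models, and
    essentiality-enrichment summaries for externally produced per-reaction
    essentiality labels. All user-facing results are tidy tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
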