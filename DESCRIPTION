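Package: pmneo
Title: Game-Theoretic Community Detection by Reduced Nash Ascendancy
    Extremal Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects community structure in undirected networks by casting
    the problem as a non-cooperative game in which every node is a player
    choosing its community to maximise a community-fitness payoff.  Candidate
    partitions are compared with the (reduced) p-Nash ascendancy relation,
    which counts improving unilateral deviations over a random subset of
    players, and the search for an approximate Nash equilibrium is carried
    out by a population-plus-archive extremal-optimization heuristic with a
    degree-preserving network-mixing diversity mechanism (pMNEO).  Includes
    the Cournot oligopoly as a continuous benchmark game with a closed-form
    equilibrium, a Girvan-Newman planted-partition generator, normalized
    mutual information and modularity metrics, readers and writers for edge
    list, GML and Pajek network formats, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
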