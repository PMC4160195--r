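Package: tripnet
Title: Rooted Phylogenetic Networks from Arbitrary Sets of Rooted Triplets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs rooted phylogenetic networks with few reticulation
    nodes that are consistent with an arbitrary (not necessarily dense) set
    of rooted triplets, via the TripNet heuristic: a triplet digraph on leaf
    pairs yields a layered height function, HBUILD reconstructs a tree when
    one exists, and otherwise an SN-set decomposition with three reticulation
    criteria selects reticulation leaves that are re-inserted and patched
    until every input triplet is displayed by the network. Includes the
    TCD rule for deriving triplets from a distance matrix, exact triplet
    consistency checking on networks, eNewick input/output, and generators
    for random trees, networks and distance matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
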