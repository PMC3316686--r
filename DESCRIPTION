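Package: reefedge
Title: EDGE Prioritization, Supertree Assembly and Phylogenetic Signal
    Analysis for Reef Corals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Conservation-prioritization toolkit for reef-building corals
    (Scleractinia) and similar clades: bootstrap-weighted matrix
    representation with parsimony (MRP) supertree assembly with strict
    consensus, fair-proportion evolutionary distinctiveness and EDGE
    (evolutionarily distinct and globally endangered) scoring over random
    polytomy resolutions, phylogenetic signal statistics for continuous
    (Blomberg's K with tip randomization) and binary (Fritz and Purvis' D
    with permutation and Brownian-threshold nulls) traits, phylogenetically
    independent contrasts, Faith's phylogenetic diversity loss under
    extinction scenarios against equal-richness random prunings, and tree
    imbalance (Colless index) against a Yule null. Includes a synthetic-data
    generator emulating the study conditions (Red List category census,
    clumped versus random binary traits, polytomies, zero-length terminals)
    so the whole pipeline runs end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    phangorn,
    phytools,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
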