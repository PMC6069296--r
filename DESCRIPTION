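Package: phylosel
Title: Core-Gene Subset Selection for Well-Supported Phylogenies by
    Distributed Metaheuristics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Searches the space of core-gene subsets for the largest subset
    whose concatenated alignment yields the best-supported phylogenetic tree.
    A subset is scored by the mean of the lowest bootstrap support of its tree
    and the percentage of core genes it retains. Three distributed
    metaheuristics explore the binary search space: an elitist genetic
    algorithm hybridized with a Lasso attribution of gene effects on branch
    supports, a binary particle swarm optimizer in constriction and inertia
    velocity variants, and a simulated annealing with tiered geometric cooling
    and normalized Tsallis acceptance. Trees are inferred by neighbor-joining
    on Jukes-Cantor distances with Felsenstein bootstrap supports; a synthetic
    data layer (sequence simulation with planted discordant genes, and
    pseudo-boolean fitness landscapes with brute-forceable optima) makes every
    component testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
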