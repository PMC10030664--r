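Package: agenet
Title: Network Entropy, Hub and Proximity Analysis of Transcriptional Ageing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analyses age-related reorganisation of a tissue's molecular
    network by integrating bulk expression profiles with a protein-protein
    interaction scaffold.  Provides sample-specific maximum-entropy network
    ensemble entropy and per-node local entropies with a young-versus-old
    differential test; DEG-seeded condition networks ranked by maximal
    clique centrality, bottleneck and betweenness centrality and decomposed
    into dense modules by a faithful MCODE re-implementation; network
    proximity between condition gene sets with degree-matched permutation
    nulls and shortest-path proximity-gene extraction; and synthetic
    benchmark generators with planted, recoverable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
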