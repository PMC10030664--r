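#!/usr/bin/env Rscript
# Stage 1: generate the synthetic benchmark data set.
#
# Produces the PPI scaffold (scale-free backbone, satellite complexes,
# reference triad, two planted 6-cliques), the 9-age-group expression cohort
# with planted entropy-shift genes and planted DEGs, and writes everything
# (plus the ground truth) under results/data/.

suppressMessages(library(agenet))

seed <- 1L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

scaffold <- make_scaffold(n_genes = 500, m = 3, n_satellites = 55,
                          leaves_per_satellite = 5, reference_triad = TRUE,
                          planted_clique_sizes = c(6, 6), seed = seed)
sim <- make_cohort(scaffold, seed = seed + 1L)

write_scaffold(scaffold, file.path(out, "scaffold.tsv"))
write_expression(sim$cohort, file.path(out, "expression.tsv"),
                 file.path(out, "groups.tsv"))
jsonlite::write_json(unclass(sim$truth), file.path(out, "truth.json"),
                     auto_unbox = TRUE, digits = NA)

message(sprintf("scaffold: %d nodes, %d edges", igraph::vcount(scaffold),
                igraph::ecount(scaffold)))
message(sprintf("cohort: %d genes x %d samples across ages %s months",
                nrow(sim$cohort$values), ncol(sim$cohort$values),
                paste(range(sim$truth$groups), collapse = "-")))
message(sprintf("planted: %d entropy-shift genes, %d DEGs",
                length(sim$truth$entropy_shift_genes),
                length(sim$truth$deg_genes)))
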