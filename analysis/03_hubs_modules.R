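#!/usr/bin/env Rscript
# Stage 3: the ageing condition network, its hubs, and its dense modules.
#
# Calls DEGs between the youngest and oldest groups with the built-in Welch
# test, expands them by their first PPI neighbours, ranks nodes by MCC,
# Bottleneck and Betweenness, and extracts MCODE complexes (score >= 5).
# Writes results under results/network/.

suppressMessages(library(agenet))

data_dir <- "results/data"
out <- "results/network"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

scaffold <- read_scaffold(file.path(data_dir, "scaffold.tsv"), 0)
cohort <- read_expression(file.path(data_dir, "expression.tsv"),
                          file.path(data_dir, "groups.tsv"))

de <- simple_de(cohort, c(3, 6), c(24, 27), q_cutoff = 0.05)
write.table(de, file.path(out, "differential_expression.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
degs <- gene_set(attr(de, "selected"), scaffold, "ageing")
message(sprintf("%d DEGs at q < 0.05, %d mapped to the scaffold",
                sum(de$selected), length(degs)))

cn <- build_condition_network(degs, scaffold)
message(sprintf("ageing network: %d seeds + %d neighbours, %d edges",
                length(cn$seeds), length(cn$neighbours),
                igraph::ecount(cn$graph)))

hubs <- hub_table(cn)
write.table(hubs, file.path(out, "hub_table.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
rankings <- list(mcc(cn$graph), bottleneck(cn$graph),
                 betweenness_ranking(cn$graph))
tops <- top_nodes(rankings, k = 10)
message("top-10 intersection across MCC, Bottleneck and Betweenness:")
message(paste(tops$intersection, collapse = ", "))

modules <- mcode_clusters(cn$graph, min_score = 5)
rep <- cluster_report(modules, cn, top = 5)
write.table(rep, file.path(out, "mcode_clusters.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("MCODE: %d clusters with score >= 5", nrow(modules$table)))
if (nrow(rep)) print(rep[, c("rank", "seed", "size", "score")])
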