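#!/usr/bin/env Rscript
# Stage 4: network proximity of the ageing signature to other conditions.
#
# Builds planted proximal and distal condition gene sets around the top
# ageing DEGs, computes the closest-distance proximity with a 1,000-fold
# degree-matched permutation null, flags significantly proximal conditions
# (Z < -1.5 and FDR < 0.05), and extracts the genes on ageing<->condition
# shortest paths.  Writes results under results/proximity/.

suppressMessages(library(agenet))

data_dir <- "results/data"
out <- "results/proximity"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 1L

scaffold <- read_scaffold(file.path(data_dir, "scaffold.tsv"), 0)
cohort <- read_expression(file.path(data_dir, "expression.tsv"),
                          file.path(data_dir, "groups.tsv"))

de <- simple_de(cohort, c(3, 6), c(24, 27), q_cutoff = 0.05)
ord <- order(de$p)
signature <- head(intersect(de$gene[ord][de$selected[ord]],
                            igraph::V(scaffold)$name), 40)
ref <- gene_set(signature, scaffold, "ageing")
message(sprintf("ageing signature: top %d DEGs", length(ref)))

sets <- make_condition_sets(scaffold, ref, proximal_size = 30,
                            distal_size = 30, seed = seed + 2L)
set.seed(seed + 3L)
prox <- pairwise_proximity_matrix(scaffold,
                                  list(proximal = sets$proximal,
                                       distal = sets$distal),
                                  ref, run_config(n_permutations = 1000))
write.table(prox, file.path(out, "proximity.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
print(prox)

for (nm in c("proximal", "distal")) {
  pg <- proximity_genes(scaffold, ref,
                        if (nm == "proximal") sets$proximal else sets$distal)
  write.table(pg, file.path(out, sprintf("proximity_genes_%s.tsv", nm)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("%s: %d genes on shortest paths", nm, nrow(pg)))
}

pg_p <- read.delim(file.path(out, "proximity_genes_proximal.tsv"))
pg_d <- read.delim(file.path(out, "proximity_genes_distal.tsv"))
common <- sort(intersect(pg_p$gene, pg_d$gene))
write.table(data.frame(gene = common), file.path(out, "common_theme.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("common theme (nodes shared by all comparisons): %d genes",
                length(common)))
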