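# agenet

Network-level analysis of transcriptional ageing on a protein–protein
interaction (PPI) scaffold.

Ageing reorganises a tissue's molecular network: expression of interacting
genes decoheres, specific interactions give way to promiscuous ones, and
disease modules drift closer to the ageing signature.  `agenet` quantifies
this with three complementary analyses, built for bulk expression cohorts
(normalised, VST-like values) laid over a PPI network:

1. **Sample-specific network entropy.**  Each sample's expression is
   integrated with the scaffold (zero-expression genes removed, edges
   weighted by absolute expression distance, weights binned into
   `floor(sqrt(n))` bins).  The sample's entropy is the Shannon entropy of
   the maximum-entropy ensemble constrained by the degree sequence and the
   weight-bin distribution:

   `S = −Σ_{i<j} [ p⁰_ij ln p⁰_ij + Σ_q p_ij(q) ln p_ij(q) ]`,
   with `p_ij(q) = x_i x_j y_q / (1 + x_i x_j Y)`.

   Per-gene **local entropies** `S_i = −Σ_j p_ij ln p_ij` (normalised
   incident weights) feed a young-versus-old Wilcoxon rank-sum test with
   BH correction and an absolute median-shift filter (> 0.03 nats).

2. **Hub and module analysis.**  DEGs plus their first PPI neighbours form
   a condition network, ranked by Maximal Clique Centrality
   `MCC(v) = Σ_{C∈S(v)} (|C|−1)!`, Bottleneck centrality (shortest-path
   trees; a node is a bottleneck when more than a quarter of a tree's root
   paths cross it) and unnormalised Betweenness `Σ σ_st(v)/σ_st`, and
   decomposed into dense modules by a faithful MCODE re-implementation
   (cluster score = density × size, reported at score ≥ 5).

3. **Network proximity.**  The closest distance
   `d_AB = (Σ_{a∈A} min_b d(a,b) + Σ_{b∈B} min_a d(a,b)) / (‖A‖+‖B‖)`
   between condition gene sets, tested against 1,000 degree-matched
   permutations (`Z = (d_AB − d_m)/σ_m`; significantly proximal at
   Z < −1.5 and FDR < 0.05), with extraction of the genes on all
   A↔B shortest paths.

A synthetic-data module generates scaffolds, age-ordered cohorts and
condition gene sets with planted, recoverable ground truth, so every stage
is validated without downloads.  See `vignettes/network-ageing-methods.Rmd`
for the models, numerical choices and generator design.

## Worked example

The `analysis/` scripts run the whole workflow on the synthetic benchmark
(500-gene scaffold, 9 age groups × 4 samples, 50 planted entropy-shift
genes, 50 planted DEGs, planted proximal/distal condition sets):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_entropy.R
Rscript analysis/03_hubs_modules.R
Rscript analysis/04_proximity.R
```

Stage 2 prints the per-node-normalised network entropy by age group —
disorder rises monotonically with age — and the planted-gene recovery:

```
median per-node entropy by age group (months):
     3      6      9     12     15     18     21     24     27
 9.977 10.742 11.192 11.552 11.926 12.160 12.389 12.503 12.651
Spearman rho (group order vs entropy): 1.000
differential entropy: 74 significant genes (q < 0.05, |shift| > 0.03)
planted-gene recovery: sensitivity 0.98, FDR 0.338
  25 of 25 false positives are planted DEGs or their partners
```

(48 of the 50 planted entropy-shift genes are recovered; the extra calls
are all planted DEGs or their interaction partners, whose expression shift
also perturbs local edge weights — with the DEG mechanism switched off the
FDR is ≤ 0.06.)

Stage 3 builds the ageing network (200 DEGs + 214 neighbours), reports the
hub intersection across the three measures and the MCODE modules; stage 4
prints the proximity table:

```
  condition n_genes        d      d_m   sigma_m         z  p_empirical  significant
1  proximal      30 1.157143 1.568529 0.109519 -3.756297  0.000999001         TRUE
2    distal      30 3.300000 2.397414 0.140960  6.403135  1.000000000        FALSE
```

The planted proximal condition sits 3.8 null standard deviations closer to
the ageing signature than degree-matched chance and is flagged; the
planted distal condition is not.

Programmatic use mirrors the scripts:

```r
library(agenet)
scaffold <- read_scaffold("ppi_edges.tsv", confidence_cutoff = 0.9)
cohort   <- read_expression("expression.tsv", "groups.tsv")
ent  <- cohort_entropy(cohort, scaffold)
diff <- differential_entropy(ent, young_groups = c(3, 6), old_groups = c(24, 27))
degs <- read_gene_set("ageing_degs.txt", scaffold)
cn   <- build_condition_network(degs, scaffold)
hubs <- hub_table(cn)
mods <- mcode_clusters(cn$graph, min_score = 5)
prox <- proximity_z(scaffold, degs, read_gene_set("nafld_degs.txt", scaffold))
```

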