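#' Run the full synthetic ageing analysis end to end
#'
#' Generates a scaffold and an age-ordered cohort, then runs every analysis
#' stage: per-sample ensemble entropy and the young-versus-old differential
#' local-entropy test; differential expression, the DEG + first-neighbour
#' ageing network with hub rankings and MCODE modules; and network proximity
#' of the ageing signature against planted proximal and distal condition
#' sets, including shortest-path proximity genes.  All result tables are
#' written as TSV under \code{out_dir}; given the same seed the outputs are
#' byte-identical across runs.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed driving every stochastic stage.
#' @param config an \code{\link{run_config}}.
#' @param scaffold_args,cohort_args optional argument overrides for
#'   \code{\link{make_scaffold}} / \code{\link{make_cohort}}.
#' @param proximal_size,distal_size condition gene-set sizes.
#' @param write_networks also write the per-sample weighted edge lists
#'   (large; off by default).
#'
#' @return Invisibly, a list with the main in-memory results
#'   (\code{entropy}, \code{differential}, \code{de}, \code{hubs},
#'   \code{modules}, \code{proximity}, \code{truth}, \code{files}).
#' @export
run_ageing_pipeline <- function(out_dir, seed = 1L, config = run_config(),
                                scaffold_args = list(), cohort_args = list(),
                                proximal_size = 30L, distal_size = 30L,
                                write_networks = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)

  if (is.null(scaffold_args$planted_clique_sizes))
    scaffold_args$planted_clique_sizes <- c(6L, 6L)
  scaffold <- do.call(make_scaffold, c(list(seed = seed), scaffold_args))
  sim <- do.call(make_cohort, c(list(scaffold = scaffold, seed = seed + 1L),
                                cohort_args))
  cohort <- sim$cohort; truth <- sim$truth
  write_scaffold(scaffold, fp("scaffold.tsv"))
  write_expression(cohort, fp("expression.tsv"), fp("groups.tsv"))
  jsonlite::write_json(unclass(truth), fp("truth.json"), auto_unbox = TRUE,
                       digits = NA)

  # --- entropy stage ---
  ent <- cohort_entropy(cohort, scaffold)
  write_tsv(ent$samples, fp("sample_entropy.tsv"))
  loc <- data.frame(gene = rownames(ent$local), ent$local,
                    check.names = FALSE)
  write_tsv(loc, fp("local_entropy.tsv"))
  groups <- truth$groups
  young <- groups[1:2]; old <- utils::tail(groups, 2)
  diff <- differential_entropy(ent, young, old, config)
  write_tsv(diff, fp("differential_entropy.tsv"))

  # --- ageing network stage ---
  de <- simple_de(cohort, young, old, q_cutoff = config$fdr_threshold)
  ageing_genes <- intersect(attr(de, "selected"), V(scaffold)$name)
  write_tsv(de, fp("differential_expression.tsv"))
  hubs <- NULL; modules <- NULL
  if (length(ageing_genes) >= 1L) {
    ageing_set <- gene_set(ageing_genes, scaffold, "ageing")
    cn <- build_condition_network(ageing_set, scaffold)
    hubs <- hub_table(cn)
    write_tsv(hubs, fp("hub_table.tsv"))
    modules <- mcode_clusters(cn$graph, min_score = config$mcode_score_min)
    write_tsv(cluster_report(modules, cn), fp("mcode_clusters.tsv"))
  }

  # --- proximity stage ---
  # ageing signature: the top-ranked DEGs, so the reference set stays a
  # modest fraction of the scaffold (as DEG lists are of an interactome)
  ord <- order(de$p)
  sig_genes <- intersect(de$gene[ord][de$selected[ord]], V(scaffold)$name)
  sig_genes <- utils::head(sig_genes, 40L)
  ref_set <- gene_set(sig_genes, scaffold, "ageing")
  sets <- make_condition_sets(scaffold, ref_set, proximal_size, distal_size,
                              seed = seed + 2L)
  set.seed(seed + 3L)
  prox <- pairwise_proximity_matrix(scaffold,
                                    list(proximal = sets$proximal,
                                         distal = sets$distal),
                                    ref_set, config)
  write_tsv(prox, fp("proximity.tsv"))
  pg_prox <- proximity_genes(scaffold, ref_set, sets$proximal)
  pg_dist <- proximity_genes(scaffold, ref_set, sets$distal)
  write_tsv(pg_prox, fp("proximity_genes_proximal.tsv"))
  write_tsv(pg_dist, fp("proximity_genes_distal.tsv"))
  common_theme <- intersect(pg_prox$gene, pg_dist$gene)
  write_tsv(data.frame(gene = sort(common_theme)), fp("common_theme.tsv"))

  if (write_networks) {
    dir.create(fp("sample_networks"), showWarnings = FALSE)
    for (id in colnames(cohort$values)) {
      net <- build_sample_network(cohort, id, scaffold)
      write_sample_network(net, bin_weights(net),
                           fp("sample_networks", paste0(id, ".tsv")))
    }
  }

  invisible(list(scaffold = scaffold, cohort = cohort, truth = truth,
                 entropy = ent, differential = diff, de = de,
                 hubs = hubs, modules = modules, proximity = prox,
                 files = list.files(out_dir, recursive = TRUE)))
}
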