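#' Build a condition network from DEGs plus first neighbours
#'
#' Expands a mapped DEG set by its first neighbours on the scaffold and takes
#' the full induced subgraph (neighbour-neighbour edges included); this
#' expanded network is the substrate for hub and module analysis.
#'
#' @param degs a \code{\link{gene_set}} of differentially expressed genes.
#' @param scaffold scaffold \code{igraph}.
#'
#' @return A list of class \code{"condition_network"}: \code{graph} (induced
#'   igraph), \code{seeds}, \code{neighbours}, and a per-node
#'   \code{provenance} vector ("seed" or "neighbour").
#' @export
build_condition_network <- function(degs, scaffold) {
  seeds <- intersect(as.character(degs), V(scaffold)$name)
  if (length(seeds) == 0L) stop("no DEGs mapped to the scaffold")
  vids <- match(seeds, V(scaffold)$name)
  nb <- unique(unlist(adjacent_vertices(scaffold, vids)))
  nodes <- union(vids, nb)
  g <- induced_subgraph(scaffold, nodes)
  prov <- ifelse(V(g)$name %in% seeds, "seed", "neighbour")
  names(prov) <- V(g)$name
  structure(list(graph = g, seeds = seeds,
                 neighbours = setdiff(V(g)$name, seeds),
                 provenance = prov),
            class = "condition_network")
}

#' @export
print.condition_network <- function(x, ...) {
  cat(sprintf("condition_network: %d seeds + %d neighbours, %d edges\n",
              length(x$seeds), length(x$neighbours), ecount(x$graph)))
  invisible(x)
}

#' Simple differential-expression stand-in
#'
#' Per-gene Welch t-test on normalised expression values between two sample
#' groups, Benjamini-Hochberg corrected.  This is a deliberately simple
#' stand-in so synthetic benchmark runs are self-contained; analyses of real
#' count data should supply externally derived DEG lists (e.g. from DESeq2).
#'
#' Genes with zero variance in both groups get p = 1.
#'
#' @param cohort an \code{\link{expression_cohort}}.
#' @param groupA,groupB group labels for the two sides.
#' @param q_cutoff BH q-value threshold for the returned gene list.
#'
#' @return Data frame (gene, meanA, meanB, log_change = meanB - meanA, t, p,
#'   q, selected) with attribute \code{selected}: the genes at q < q_cutoff.
#' @export
simple_de <- function(cohort, groupA, groupB, q_cutoff = 0.05) {
  stopifnot(inherits(cohort, "expr_cohort"))
  a_ids <- names(cohort$groups)[cohort$groups %in% groupA]
  b_ids <- names(cohort$groups)[cohort$groups %in% groupB]
  if (length(a_ids) < 2L || length(b_ids) < 2L)
    stop("need at least 2 samples per group")
  A <- cohort$values[, a_ids, drop = FALSE]
  B <- cohort$values[, b_ids, drop = FALSE]
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- apply(A, 1, var); vb <- apply(B, 1, var)
  na <- ncol(A); nb <- ncol(B)
  se2 <- va / na + vb / nb
  tt <- ifelse(se2 > 0, (mb - ma) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / (va^2 / (na^2 * (na - 1)) + vb^2 / (nb^2 * (nb - 1))),
               1)
  p <- ifelse(se2 > 0, 2 * pt(abs(tt), df, lower.tail = FALSE), 1)
  q <- p.adjust(p, method = "BH")
  res <- data.frame(gene = rownames(cohort$values),
                    meanA = ma, meanB = mb, change = mb - ma,
                    t = tt, p = p, q = q,
                    selected = q < q_cutoff,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "selected") <- res$gene[res$selected]
  res
}

#' @importFrom stats var
NULL
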