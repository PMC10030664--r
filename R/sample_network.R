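#' Build a sample-specific weighted network
#'
#' Lays one sample's expression over the PPI scaffold: scaffold nodes with
#' strictly positive expression in this sample are kept, every retained edge
#' is weighted by the absolute difference of its endpoints' expression values,
#' and zero-expression genes (including genes absent from the matrix, which
#' are treated as unexpressed) are removed.  The resulting network is
#' sample-specific and generally differs from the static scaffold.
#'
#' @param cohort an \code{\link{expression_cohort}}.
#' @param sample_id column of the cohort to use.
#' @param scaffold scaffold \code{igraph}.
#'
#' @return A list of class \code{"sample_network"}: \code{graph} (igraph with
#'   edge attribute \code{weight}), \code{sample_id}, \code{group},
#'   \code{n_removed} (zero-expression or unmatched scaffold genes).
#' @export
build_sample_network <- function(cohort, sample_id, scaffold) {
  stopifnot(inherits(cohort, "expr_cohort"))
  if (!sample_id %in% colnames(cohort$values))
    stop("sample ", sample_id, " not in cohort")
  expr <- cohort$values[, sample_id]
  nodes <- V(scaffold)$name
  ev <- expr[match(nodes, names(expr))]
  ev[is.na(ev)] <- 0
  keep <- ev > 0
  if (sum(keep) < 2L)
    stop("fewer than 2 expressed scaffold genes in sample ", sample_id)
  g <- induced_subgraph(scaffold, which(keep))
  ev <- ev[keep]
  el <- as_edgelist(g, names = FALSE)
  E(g)$weight <- abs(ev[el[, 1]] - ev[el[, 2]])
  V(g)$expression <- unname(ev)
  structure(list(graph = g,
                 sample_id = sample_id,
                 group = unname(cohort$groups[sample_id]),
                 n_removed = sum(!keep)),
            class = "sample_network")
}

#' @export
print.sample_network <- function(x, ...) {
  cat(sprintf("sample_network '%s' (group %s): %d nodes, %d edges, %d removed\n",
              x$sample_id, x$group, vcount(x$graph), ecount(x$graph),
              x$n_removed))
  invisible(x)
}

#' Discretise a sample network's edge weights
#'
#' Partitions the observed weight range into equal-width bins; the number of
#' bins is the floor of the square root of the node count (minimum 1), and
#' the right-most bin is closed.  When all weights coincide every edge falls
#' into bin 1.
#'
#' @param net a \code{\link{build_sample_network}} result.
#'
#' @return A list of class \code{"weight_binning"}: \code{n_bins},
#'   \code{breaks} (length \code{n_bins + 1}), \code{counts} (edges per bin,
#'   summing to the edge count) and \code{bin} (per-edge bin index).
#' @export
bin_weights <- function(net) {
  stopifnot(inherits(net, "sample_network"))
  w <- E(net$graph)$weight
  if (length(w) == 0L) stop("sample network has no edges")
  n_bins <- max(1L, floor(sqrt(vcount(net$graph))))
  lo <- min(w); hi <- max(w)
  if (hi == lo) {
    breaks <- c(lo, rep(hi, n_bins))
    bin <- rep(1L, length(w))
  } else {
    breaks <- seq(lo, hi, length.out = n_bins + 1L)
    bin <- pmin(pmax(findInterval(w, breaks, rightmost.closed = TRUE), 1L),
                n_bins)
  }
  structure(list(n_bins = n_bins, breaks = breaks,
                 counts = tabulate(bin, n_bins), bin = bin),
            class = "weight_binning")
}

#' Write a sample network as a weighted edge list
#'
#' Columns: gene_a, gene_b, weight, bin.
#'
#' @param net a \code{sample_network}.
#' @param binning its \code{\link{bin_weights}} result.
#' @param path output TSV.
#' @export
write_sample_network <- function(net, binning, path) {
  el <- as_edgelist(net$graph)
  lo <- pmin(el[, 1], el[, 2]); hi <- pmax(el[, 1], el[, 2])
  ord <- order(lo, hi)
  write_tsv(data.frame(gene_a = lo[ord], gene_b = hi[ord],
                       weight = E(net$graph)$weight[ord],
                       bin = binning$bin[ord]), path)
}
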