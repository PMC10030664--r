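# MCODE dense-module detection --------------------------------------------
#
# Faithful re-implementation of the molecular complex detection algorithm:
# stage 1 weights each vertex by the density of the highest k-core of its
# closed neighbourhood times that core's k; stage 2 grows complexes from the
# highest-weighted unassigned seeds, recursively including neighbours whose
# weight is within a fixed percentage of the seed weight; stage 3 applies
# the haircut (2-core of each complex) and drops complexes without a 2-core.
# Cluster score = density x node count, with density 2E / (V (V - 1)), so a
# detached K5 scores exactly 5.

graph_density_simple <- function(g) {
  n <- vcount(g)
  if (n < 2L) return(0)
  2 * ecount(g) / (n * (n - 1))
}

highest_kcore <- function(g) {
  core <- coreness(g)
  kmax <- max(core)
  list(k = kmax, graph = induced_subgraph(g, which(core == kmax)))
}

#' MCODE vertex weights
#'
#' w(v) = k x density of the highest k-core of v's closed neighbourhood.
#'
#' @param graph simple undirected \code{igraph}.
#' @return Named numeric vector of vertex weights.
#' @export
mcode_vertex_weights <- function(graph) {
  n <- vcount(graph)
  w <- setNames(numeric(n), V(graph)$name)
  adj <- adjacent_vertices(graph, V(graph))
  for (v in seq_len(n)) {
    nb <- as.integer(adj[[v]])
    if (length(nb) == 0L) next
    sub <- induced_subgraph(graph, c(v, nb))
    hk <- highest_kcore(sub)
    w[v] <- hk$k * graph_density_simple(hk$graph)
  }
  w
}

#' MCODE clusters
#'
#' Runs the three MCODE stages with the published defaults and filters the
#' resulting complexes by cluster score.
#'
#' Seeds are processed in decreasing weight (ties lexicographic by symbol);
#' a vertex joins the first complex that claims it, so emitted clusters are
#' node-disjoint.  Vertices discarded by the haircut become available to
#' later seeds.
#'
#' @param graph simple undirected \code{igraph}.
#' @param degree_cutoff minimum degree for a vertex to be scored/seeded.
#' @param node_score_cutoff inclusion threshold as a fraction of the seed
#'   weight (a neighbour joins when w >= (1 - cutoff) * w(seed)).
#' @param k_core complexes without a k-core of this order are discarded.
#' @param max_depth maximum BFS depth from the seed.
#' @param haircut remove singly-connected vertices (take the 2-core) from
#'   each complex.
#' @param fluff unsupported switch kept for interface parity; must be FALSE.
#' @param min_score minimum reported cluster score.
#'
#' @return A list of class \code{"mcode_result"}: \code{clusters} (list of
#'   character vectors, ranked), \code{table} (data frame with seed, size,
#'   score, rank) and \code{weights}.
#' @export
mcode_clusters <- function(graph, degree_cutoff = 2L, node_score_cutoff = 0.2,
                           k_core = 2L, max_depth = 100L, haircut = TRUE,
                           fluff = FALSE, min_score = 5) {
  stopifnot(!fluff)
  n <- vcount(graph)
  nodes <- V(graph)$name
  w <- mcode_vertex_weights(graph)
  deg <- degree(graph)
  adj <- lapply(adjacent_vertices(graph, V(graph)), as.integer)
  eligible <- deg >= degree_cutoff
  ord <- order(-w, nodes)
  ord <- ord[eligible[ord]]
  assigned <- rep(FALSE, n)
  clusters <- list(); seeds <- character(0)
  for (s in ord) {
    if (assigned[s]) next
    thresh <- w[s] * (1 - node_score_cutoff)
    members <- s
    assigned[s] <- TRUE
    frontier <- s
    depth <- 0L
    while (length(frontier) && depth < max_depth) {
      nxt <- integer(0)
      for (u in frontier) {
        for (v2 in adj[[u]]) {
          if (!assigned[v2] && w[v2] >= thresh) {
            assigned[v2] <- TRUE
            nxt <- c(nxt, v2)
          }
        }
      }
      members <- c(members, nxt)
      frontier <- nxt
      depth <- depth + 1L
    }
    sub <- induced_subgraph(graph, members)
    if (haircut) {
      core <- coreness(sub)
      keep <- V(sub)$name[core >= 2L]
      # haircut-discarded vertices may join later complexes
      dropped <- match(setdiff(V(sub)$name, keep), nodes)
      assigned[dropped] <- FALSE
      if (length(keep) == 0L) next
      sub <- induced_subgraph(sub, match(keep, V(sub)$name))
    }
    if (max(coreness(sub)) < k_core) {
      assigned[match(V(sub)$name, nodes)] <- FALSE
      next
    }
    clusters[[length(clusters) + 1L]] <- sort(V(sub)$name)
    seeds <- c(seeds, nodes[s])
  }
  if (length(clusters)) {
    size <- lengths(clusters)
    dens <- vapply(clusters, function(m)
      graph_density_simple(induced_subgraph(graph, match(m, nodes))), 0)
    score <- dens * size
    keep <- score >= min_score
    clusters <- clusters[keep]; seeds <- seeds[keep]
    size <- size[keep]; dens <- dens[keep]; score <- score[keep]
    ord2 <- order(-score, seeds)
    clusters <- clusters[ord2]
    tab <- data.frame(rank = seq_along(clusters), seed = seeds[ord2],
                      size = size[ord2], density = dens[ord2],
                      score = score[ord2], stringsAsFactors = FALSE)
  } else {
    tab <- data.frame(rank = integer(0), seed = character(0),
                      size = integer(0), density = numeric(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  }
  structure(list(clusters = clusters, table = tab, weights = w),
            class = "mcode_result")
}

#' @export
print.mcode_result <- function(x, ...) {
  cat(sprintf("mcode_result: %d clusters\n", length(x$clusters)))
  if (nrow(x$table)) print(x$table)
  invisible(x)
}

#' Cluster membership report
#'
#' Per-cluster summary against a condition network: member list, seed versus
#' neighbour provenance counts, score and rank.
#'
#' @param result an \code{\link{mcode_clusters}} result.
#' @param cn the \code{\link{build_condition_network}} the graph came from,
#'   or NULL for plain graphs.
#' @param top keep at most this many clusters (by rank); NULL for all.
#' @return Data frame: rank, seed, size, score, n_seed_genes,
#'   n_neighbour_genes, members (comma-separated).
#' @export
cluster_report <- function(result, cn = NULL, top = NULL) {
  stopifnot(inherits(result, "mcode_result"))
  tab <- result$table
  if (!is.null(top)) tab <- head(tab, top)
  members <- result$clusters[tab$rank]
  prov <- if (!is.null(cn)) cn$provenance else NULL
  data.frame(rank = tab$rank, seed = tab$seed, size = tab$size,
             score = tab$score,
             n_seed_genes = vapply(members, function(m)
               if (is.null(prov)) NA_integer_ else sum(prov[m] == "seed"),
               0L),
             n_neighbour_genes = vapply(members, function(m)
               if (is.null(prov)) NA_integer_ else sum(prov[m] == "neighbour"),
               0L),
             members = vapply(members, paste, "", collapse = ","),
             stringsAsFactors = FALSE)
}
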