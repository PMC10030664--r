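# Hub ranking measures ----------------------------------------------------
#
# Each measure is a function F assigning every node a score; a node u
# outranks v when F(u) > F(v).  Ties share a dense rank and are ordered
# lexicographically by gene symbol so ranked outputs are reproducible.

centrality_ranking <- function(scores, metric) {
  ord <- order(-scores, names(scores))
  scores <- scores[ord]
  rank <- cumsum(!duplicated(-scores))
  structure(data.frame(node = names(scores), score = unname(scores),
                       rank = rank, row.names = NULL,
                       stringsAsFactors = FALSE),
            metric = metric, class = c("centrality_ranking", "data.frame"))
}

#' Maximal clique centrality (MCC)
#'
#' MCC(v) is the sum over all maximal cliques containing v of
#' (|C| - 1)!.  Maximal cliques are enumerated with igraph's Bron-Kerbosch
#' implementation; an isolated node's only maximal clique is itself, giving
#' MCC = 0! = 1.
#'
#' @param graph simple undirected \code{igraph}.
#' @param max_cliques_cap abort if the maximal-clique count exceeds this cap.
#' @return A \code{centrality_ranking} data frame (node, score, rank).
#' @export
mcc <- function(graph, max_cliques_cap = 1e6) {
  n_cl <- count_max_cliques(graph)
  if (n_cl > max_cliques_cap)
    stop("maximal-clique count ", n_cl, " exceeds cap ", max_cliques_cap)
  cl <- max_cliques(graph)
  scores <- setNames(numeric(vcount(graph)), V(graph)$name)
  for (C in cl) {
    scores[C] <- scores[C] + factorial(length(C) - 1L)
  }
  centrality_ranking(scores, "MCC")
}

#' Bottleneck centrality (BN)
#'
#' For every source s, a deterministic BFS shortest-path tree over s's
#' connected component is built (each node's parent is the lexicographically
#' smallest neighbour at the previous BFS level).  A node v (v != s) is a
#' bottleneck of that tree when the number of tree paths from s to other
#' nodes crossing v -- its descendant count -- strictly exceeds a quarter of
#' the tree's node count.  BN(v) is the number of source trees in which v is
#' a bottleneck.
#'
#' The shortest-path tree is not unique; the lexicographic parent rule is
#' this package's fixed convention (the brute-force oracle in the test suite
#' uses the same rule).
#'
#' @param graph simple undirected \code{igraph}.
#' @return A \code{centrality_ranking} data frame.
#' @export
bottleneck <- function(graph) {
  n <- vcount(graph)
  nodes <- V(graph)$name
  # adjacency as index lists ordered by symbol for the lexicographic rule
  adj <- lapply(adjacent_vertices(graph, V(graph)), as.integer)
  sym_order <- order(nodes)
  lex_rank <- integer(n); lex_rank[sym_order] <- seq_len(n)
  scores <- setNames(numeric(n), nodes)
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n)
    parent <- rep(NA_integer_, n)
    dist[s] <- 0L
    frontier <- s
    order_visited <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (u in frontier) {
        for (w in adj[[u]]) {
          if (is.na(dist[w])) {
            dist[w] <- dist[u] + 1L
            nxt <- c(nxt, w)
          }
        }
      }
      nxt <- unique(nxt)
      for (w in nxt) {
        preds <- adj[[w]][!is.na(dist[adj[[w]]]) & dist[adj[[w]]] == dist[w] - 1L]
        parent[w] <- preds[which.min(lex_rank[preds])]
      }
      order_visited <- c(order_visited, nxt)
      frontier <- nxt
    }
    tree_nodes <- which(!is.na(dist))
    tn <- length(tree_nodes)
    if (tn < 2L) next
    # descendant counts: process in reverse BFS order
    sub <- rep(1L, n)
    for (w in rev(order_visited)) {
      if (!is.na(parent[w])) sub[parent[w]] <- sub[parent[w]] + sub[w]
    }
    crossing <- sub - 1L  # paths from s to proper descendants of v
    bn <- tree_nodes[tree_nodes != s & crossing[tree_nodes] > tn / 4]
    scores[bn] <- scores[bn] + 1
  }
  centrality_ranking(scores, "Bottleneck")
}

#' Betweenness centrality ranking (BW)
#'
#' Unnormalised shortest-path betweenness over unordered node pairs within
#' each connected component, endpoints excluded (Brandes' algorithm via
#' igraph), wrapped as a reproducibly tie-broken ranking.
#'
#' @param graph simple undirected \code{igraph}.
#' @return A \code{centrality_ranking} data frame.
#' @export
betweenness_ranking <- function(graph) {
  scores <- igraph::betweenness(graph, directed = FALSE, weights = NA,
                                normalized = FALSE)
  names(scores) <- V(graph)$name
  centrality_ranking(scores, "Betweenness")
}

#' Top-k nodes per centrality metric
#'
#' Selects each ranking's k best nodes, expanding ties at the k-th score
#' (the returned set may exceed k; tied entries are flagged), and reports the
#' intersection across metrics -- the nodes of both local and global
#' importance.
#'
#' @param rankings list of \code{centrality_ranking} data frames.
#' @param k number of top nodes per metric.
#' @return A list with \code{top} (named list of data frames, each with a
#'   \code{tied_at_k} flag) and \code{intersection} (character vector).
#' @export
top_nodes <- function(rankings, k = 10L) {
  stopifnot(k >= 1)
  top <- lapply(rankings, function(r) {
    if (nrow(r) <= k) {
      out <- r
      out$tied_at_k <- FALSE
      return(out)
    }
    cutoff <- r$score[k]
    out <- r[r$score >= cutoff, , drop = FALSE]
    out$tied_at_k <- out$score == cutoff & sum(r$score == cutoff) > 1L &
      nrow(out) > k
    out
  })
  names(top) <- vapply(rankings, attr, "", "metric")
  inter <- Reduce(intersect, lapply(top, function(t) t$node))
  list(top = top, intersection = inter)
}

#' Combined hub table for a condition network
#'
#' Runs MCC, Bottleneck and Betweenness on a condition network and joins the
#' scores, ranks and node provenance into one table.
#'
#' @param cn a \code{\link{build_condition_network}} result.
#' @param max_cliques_cap passed to \code{\link{mcc}}.
#' @return Data frame: node, provenance, mcc, bottleneck, betweenness and the
#'   per-metric ranks, ordered by MCC rank.
#' @export
hub_table <- function(cn, max_cliques_cap = 1e6) {
  stopifnot(inherits(cn, "condition_network"))
  g <- cn$graph
  r_mcc <- mcc(g, max_cliques_cap)
  r_bn <- bottleneck(g)
  r_bw <- betweenness_ranking(g)
  df <- data.frame(node = r_mcc$node,
                   provenance = unname(cn$provenance[r_mcc$node]),
                   mcc = r_mcc$score,
                   mcc_rank = r_mcc$rank,
                   stringsAsFactors = FALSE)
  df$bottleneck <- r_bn$score[match(df$node, r_bn$node)]
  df$bottleneck_rank <- r_bn$rank[match(df$node, r_bn$node)]
  df$betweenness <- r_bw$score[match(df$node, r_bw$node)]
  df$betweenness_rank <- r_bw$rank[match(df$node, r_bw$node)]
  df
}
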