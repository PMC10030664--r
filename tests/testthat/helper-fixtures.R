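# Small named-graph builders used across the suite.

named_graph <- function(..., isolated = character(0)) {
  edges <- c(...)
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                   directed = FALSE)
  if (length(isolated)) {
    g <- igraph::add_vertices(g, length(isolated), name = isolated)
  }
  g
}

path_named <- function(n, prefix = "n") {
  nm <- sprintf("%s%02d", prefix, seq_len(n))
  g <- igraph::make_ring(n, circular = FALSE)
  igraph::V(g)$name <- nm
  g
}

cycle_named <- function(n, prefix = "n") {
  nm <- sprintf("%s%02d", prefix, seq_len(n))
  g <- igraph::make_ring(n, circular = TRUE)
  igraph::V(g)$name <- nm
  g
}

star_named <- function(n_leaves, prefix = "n") {
  g <- igraph::make_star(n_leaves + 1, mode = "undirected", center = 1)
  igraph::V(g)$name <- c("center", sprintf("%s%02d", prefix, seq_len(n_leaves)))
  g
}

complete_named <- function(n, prefix = "n") {
  g <- igraph::make_full_graph(n)
  igraph::V(g)$name <- sprintf("%s%02d", prefix, seq_len(n))
  g
}

# Erdos-Renyi with guaranteed vertex names
er_named <- function(n, p) {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
  g
}

# tiny cohort over an explicit expression matrix
toy_cohort <- function(values, groups) {
  expression_cohort(values, groups)
}

# two K6 cliques joined through a single intermediate bridge node
two_k6_bridge_node <- function() {
  g <- igraph::make_full_graph(6) + igraph::make_full_graph(6) +
    igraph::make_empty_graph(1, directed = FALSE)
  g <- igraph::add_edges(g, c(1, 13, 7, 13))
  igraph::V(g)$name <- c(sprintf("a%02d", 1:6), sprintf("b%02d", 1:6), "bridge")
  g
}

# two K6 cliques joined by one direct bridge edge
two_k6_bridge_edge <- function() {
  g <- igraph::make_full_graph(6) + igraph::make_full_graph(6)
  g <- igraph::add_edges(g, c(1, 7))
  igraph::V(g)$name <- c(sprintf("a%02d", 1:6), sprintf("b%02d", 1:6))
  g
}

sort_by_node <- function(ranking) {
  setNames(ranking$score, ranking$node)[order(ranking$node)]
}

oracle_sorted <- function(scores) scores[order(names(scores))]

centrality_fixture <- function(scores, metric) {
  agenet:::centrality_ranking(scores, metric)
}
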