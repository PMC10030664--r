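# Definitional brute-force oracles, independent of the package's
# implementations.  All operate on small graphs only.

oracle_adj <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  diag(A) <- 0
  A
}

# --- MCC: enumerate all maximal cliques by subset scan --------------------
oracle_mcc <- function(g) {
  A <- oracle_adj(g)
  n <- nrow(A)
  nodes <- igraph::V(g)$name
  scores <- stats::setNames(numeric(n), nodes)
  is_clique <- function(S) {
    if (length(S) < 2) return(TRUE)
    all(A[S, S][upper.tri(A[S, S])] == 1)
  }
  for (mask in seq_len(2^n - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (!is_clique(S)) next
    ext <- setdiff(seq_len(n), S)
    maximal <- !any(vapply(ext, function(x) all(A[x, S] == 1), TRUE))
    if (maximal) scores[S] <- scores[S] + factorial(length(S) - 1)
  }
  scores
}

# --- Bottleneck: same lexicographic-parent BFS tree, path-walk counting ---
oracle_bottleneck <- function(g) {
  A <- oracle_adj(g)
  n <- nrow(A)
  nodes <- igraph::V(g)$name
  lex <- rank(nodes)
  scores <- stats::setNames(numeric(n), nodes)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    # plain BFS by levels
    level <- 0
    repeat {
      cur <- which(dist == level)
      if (!length(cur)) break
      for (u in cur) {
        for (w in which(A[u, ] == 1)) {
          if (is.infinite(dist[w])) dist[w] <- level + 1
        }
      }
      level <- level + 1
    }
    parent <- rep(NA_integer_, n)
    for (w in which(is.finite(dist) & dist > 0)) {
      preds <- which(A[w, ] == 1 & dist == dist[w] - 1)
      parent[w] <- preds[order(lex[preds])][1]
    }
    tree <- which(is.finite(dist))
    tn <- length(tree)
    if (tn < 2) next
    # count, for every v, the targets whose root path passes through v
    crossing <- rep(0, n)
    for (t in setdiff(tree, s)) {
      chain <- integer(0)
      u <- t
      while (!is.na(parent[u])) {
        u <- parent[u]
        chain <- c(chain, u)
      }
      chain <- setdiff(chain, s)  # ancestors of t other than the root
      crossing[chain] <- crossing[chain] + 1
    }
    bn <- setdiff(tree, s)
    bn <- bn[crossing[bn] > tn / 4]
    scores[bn] <- scores[bn] + 1
  }
  scores
}

# --- Betweenness: explicit enumeration of all shortest paths --------------
oracle_betweenness <- function(g) {
  A <- oracle_adj(g)
  n <- nrow(A)
  nodes <- igraph::V(g)$name
  D <- igraph::distances(g, weights = NA)
  scores <- stats::setNames(numeric(n), nodes)
  all_sp <- function(s, t) {
    # enumerate node sequences of shortest s-t paths
    if (s == t) return(list(s))
    out <- list()
    expand <- function(path) {
      u <- path[length(path)]
      if (u == t) { out[[length(out) + 1]] <<- path; return(invisible()) }
      for (w in which(A[u, ] == 1)) {
        if (D[s, w] == D[s, u] + 1 && D[w, t] == D[u, t] - 1) {
          expand(c(path, w))
        }
      }
    }
    expand(s)
    out
  }
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (!is.finite(D[s, t])) next
      paths <- all_sp(s, t)
      sigma <- length(paths)
      inner <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
      if (length(inner)) {
        tab <- table(inner)
        idx <- as.integer(names(tab))
        scores[idx] <- scores[idx] + as.numeric(tab) / sigma
      }
    }
  }
  scores
}

# --- closest distance: direct min-over-pairs arithmetic -------------------
oracle_closest_distance <- function(g, A, B) {
  D <- igraph::distances(g, weights = NA)
  ai <- match(A, igraph::V(g)$name)
  bi <- match(B, igraph::V(g)$name)
  vals <- c(apply(D[ai, bi, drop = FALSE], 1, min),
            apply(D[ai, bi, drop = FALSE], 2, min))
  vals <- vals[is.finite(vals)]
  sum(vals) / length(vals)
}

# --- proximity genes: union over igraph's all_shortest_paths --------------
oracle_proximity_genes <- function(g, A, B) {
  out <- character(0)
  for (a in A) {
    for (b in B) {
      if (!is.finite(igraph::distances(g, v = a, to = b, weights = NA)[1, 1]))
        next
      sp <- igraph::all_shortest_paths(g, from = a, to = b, weights = NA)$vpaths
      out <- union(out, unique(unlist(lapply(sp, function(p) names(p)))))
    }
  }
  sort(out)
}

# --- exact Wilcoxon rank-sum by enumeration of rank assignments -----------
oracle_wilcoxon_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  ranks <- seq_len(nx + ny)
  ws <- apply(combs, 2, function(idx) sum(ranks[idx])) - nx * (nx + 1) / 2
  p_le <- mean(ws <= w_obs)
  p_ge <- mean(ws >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# --- ensemble entropy: primal augmented-Lagrangian maximisation -----------
# Maximises Shannon entropy over per-pair category probabilities (no-link +
# one category per weight bin) subject to expected-degree and bin-count
# constraints, using softmax parameterisation and numeric BFGS.
oracle_ensemble_entropy <- function(k, m_q, outer_iterations = 40) {
  m_q <- m_q[m_q > 0]  # empty bins carry no probability at the optimum
  n <- length(k); Q <- length(m_q)
  pairs <- t(utils::combn(n, 2)); np <- nrow(pairs)
  A <- matrix(0, n + Q, np * (Q + 1)); b <- c(k, m_q)
  for (e in seq_len(np)) {
    for (q in seq_len(Q)) {
      col <- (e - 1) * (Q + 1) + 1 + q
      A[pairs[e, 1], col] <- 1
      A[pairs[e, 2], col] <- 1
      A[n + q, col] <- 1
    }
  }
  probs <- function(zv) {
    zm <- matrix(zv, nrow = np, byrow = TRUE)
    zm <- zm - apply(zm, 1, max)
    pm <- exp(zm); pm <- pm / rowSums(pm)
    as.vector(t(pm))
  }
  obj <- function(zv, lam, rho) {
    p <- probs(zv)
    H <- -sum(ifelse(p > 0, p * log(p), 0))
    gv <- as.vector(A %*% p) - b
    -(H - sum(lam * gv) - rho / 2 * sum(gv^2))
  }
  grad <- function(zv, lam, rho) {
    p <- probs(zv)
    gv <- as.vector(A %*% p) - b
    dGdp <- (1 + log(pmax(p, 1e-300))) + as.vector(t(A) %*% (lam + rho * gv))
    # softmax chain rule per pair
    dGdp_m <- matrix(dGdp, nrow = np, byrow = TRUE)
    pm <- matrix(p, nrow = np, byrow = TRUE)
    gz <- pm * (dGdp_m - rowSums(pm * dGdp_m))
    as.vector(t(gz))
  }
  zv <- rep(0, np * (Q + 1)); lam <- rep(0, n + Q); rho <- 10
  for (ot in seq_len(outer_iterations)) {
    opt <- stats::optim(zv, obj, gr = grad, lam = lam, rho = rho,
                        method = "BFGS",
                        control = list(maxit = 3000, reltol = 1e-15))
    zv <- opt$par
    p <- probs(zv)
    gv <- as.vector(A %*% p) - b
    lam <- lam + rho * gv
    if (max(abs(gv)) < 1e-8) break
    rho <- min(rho * 1.8, 1e7)
  }
  p <- probs(zv)
  list(entropy = -sum(ifelse(p > 0, p * log(p), 0)),
       violation = max(abs(as.vector(A %*% p) - b)))
}

# random small test graph suitable for the ensemble fit: every degree in
# [1, n-2] and not complete
random_fit_graph <- function(n, p_edge = 0.55) {
  repeat {
    g <- er_named(n, p_edge)
    k <- igraph::degree(g)
    if (all(k >= 1) && all(k <= n - 2) &&
        igraph::ecount(g) < n * (n - 1) / 2) return(g)
  }
}

# wrap a weighted graph as the package's sample-network class
as_sample_network <- function(g, weights, sample_id = "S1", group = 1) {
  igraph::E(g)$weight <- weights
  structure(list(graph = g, sample_id = sample_id, group = group,
                 n_removed = 0L), class = "sample_network")
}
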