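# Maximum-entropy network ensemble ---------------------------------------
#
# A sample network is treated as one instance of an ensemble of networks
# sharing two sets of observables: the degree sequence and the distribution
# of edge weights over bins.  The canonical (soft-constraint) ensemble puts
# each node pair either in the unlinked state or in exactly one weight bin:
#
#   p_ij(q) = x_i x_j y_q / (1 + x_i x_j Y),   p0_ij = 1 / (1 + x_i x_j Y),
#
# with Y = sum_q y_q.  Expected bin counts are proportional to y_q for any
# x, so at a degree-consistent solution y_q is proportional to the observed
# m_q and the fit reduces to the soft configuration model in t_i = x_i
# sqrt(Y).  That reduced system is solved exactly by a damped Newton
# iteration, which is stable where plain fixed-point iteration oscillates.

#' Fit the maximum-entropy ensemble of a sample network
#'
#' Solves for the node and bin multipliers of the canonical weighted ensemble
#' so that expected degrees match the observed degree sequence and expected
#' bin counts match the observed weight-bin histogram.
#'
#' Isolated nodes carry no constraint and are excluded from the fit (their
#' count is recorded).  A network in which every node pair is an observed
#' edge (e.g. a complete graph, or a single linked pair) forces all link
#' probabilities to 1; this saturated case is solved analytically.
#'
#' @param net a \code{\link{build_sample_network}} result.
#' @param binning its \code{\link{bin_weights}} result.
#' @param tol maximum relative constraint violation accepted.
#' @param max_iter Newton iteration cap.
#'
#' @return A list of class \code{"ensemble_model"} with multipliers \code{x}
#'   and \code{y} (gauge Y = 1), per-pair link probabilities implied by them,
#'   the residual, and bookkeeping fields.
#' @export
fit_ensemble <- function(net, binning, tol = 1e-8, max_iter = 10000L) {
  stopifnot(inherits(net, "sample_network"), inherits(binning, "weight_binning"))
  g <- net$graph
  deg_all <- degree(g)
  iso <- sum(deg_all == 0)
  k <- deg_all[deg_all > 0]
  n <- length(k)
  if (n < 2L) stop("ensemble fit needs at least 2 non-isolated nodes")
  if (any(k >= n)) stop("degree ", max(k), " impossible among ", n, " nodes")
  M <- sum(binning$counts)
  stopifnot(sum(k) == 2 * M)
  w_bin <- binning$counts / M
  if (M == n * (n - 1) / 2) {
    # every pair carries an edge: degenerate deterministic ensemble
    return(structure(list(x = rep(Inf, n), y = w_bin, theta = NULL,
                          saturated = TRUE, residual = 0, iterations = 0L,
                          nodes = names(k), k = k, w_bin = w_bin,
                          n_nodes = vcount(g), n_isolated = iso,
                          n_edges = M),
                     class = "ensemble_model"))
  }
  if (any(k == n - 1L))
    stop("node with full degree ", n - 1L,
         " has no finite canonical-ensemble solution")
  th <- log(pmax(k, 0.5) / sqrt(2 * M))
  res <- Inf
  for (it in seq_len(max_iter)) {
    P <- plogis(outer(th, th, "+")); diag(P) <- 0
    F <- rowSums(P) - k
    res <- max(abs(F) / pmax(k, 1))
    if (res <= tol) break
    W <- P * (1 - P); diag(W) <- 0
    J <- W; diag(J) <- rowSums(W)
    step <- tryCatch(solve(J, F),
                     error = function(e) F / pmax(diag(J), 1e-12))
    f0 <- sum(F^2); lam <- 1
    repeat {
      th2 <- th - lam * step
      P2 <- plogis(outer(th2, th2, "+")); diag(P2) <- 0
      if (sum((rowSums(P2) - k)^2) < f0 || lam < 1e-8) break
      lam <- lam / 2
    }
    th <- th2
  }
  if (res > tol)
    stop(sprintf("ensemble fit did not converge: residual %.3g after %d iterations",
                 res, max_iter))
  structure(list(x = exp(th), y = w_bin, theta = th,
                 saturated = FALSE, residual = res, iterations = it,
                 nodes = names(k), k = k, w_bin = w_bin,
                 n_nodes = vcount(g), n_isolated = iso, n_edges = M),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("ensemble_model: %d nodes (%d isolated), %d edges, residual %.2e%s\n",
              x$n_nodes, x$n_isolated, x$n_edges, x$residual,
              if (x$saturated) " [saturated]" else ""))
  invisible(x)
}

#' Pairwise link probabilities of a fitted ensemble
#'
#' @param model an \code{\link{fit_ensemble}} result.
#' @return Symmetric matrix of total link probabilities (summed over bins),
#'   zero diagonal.  Per-bin probabilities are \code{p_link * y_q}.
#' @export
link_probabilities <- function(model) {
  n <- length(model$k)
  if (model$saturated) {
    p <- matrix(1, n, n)
  } else {
    p <- plogis(outer(model$theta, model$theta, "+"))
  }
  diag(p) <- 0
  dimnames(p) <- list(model$nodes, model$nodes)
  p
}

#' Global ensemble entropy of a sample network
#'
#' Shannon entropy (natural log) of the fitted maximum-entropy ensemble:
#' \deqn{S = -\sum_{i<j} [ p^0_{ij} \ln p^0_{ij} + \sum_q p_{ij}(q) \ln p_{ij}(q) ]}
#' with the convention 0 ln 0 = 0.  Because per-bin probabilities factor as
#' p_link * w_q, the sum equals the binary pair entropies plus the bin-histogram
#' entropy weighted by the expected edge count; both forms agree and the
#' closed form is used.
#'
#' @param model an \code{\link{fit_ensemble}} result.
#' @return A list with \code{raw} (nats) and \code{per_node} (raw divided by
#'   the network's node count, isolated nodes included).
#' @export
global_entropy <- function(model) {
  stopifnot(inherits(model, "ensemble_model"))
  w <- model$w_bin[model$w_bin > 0]
  H_bin <- -sum(w * log(w))
  if (model$saturated) {
    raw <- model$n_edges * H_bin
  } else {
    p <- link_probabilities(model)
    pu <- p[upper.tri(p)]
    h2 <- -ifelse(pu > 0, pu * log(pu), 0) - ifelse(pu < 1, (1 - pu) * log1p(-pu), 0)
    raw <- sum(h2) + H_bin * sum(pu)
  }
  list(raw = raw, per_node = raw / model$n_nodes)
}

#' Per-node local Shannon entropy
#'
#' For node i with incident edge weights w_ij, the local entropy is the
#' Shannon entropy of the normalised incident weight distribution
#' p_ij = w_ij / sum_j w_ij (natural log).  Zero-weight edges contribute
#' nothing; nodes whose incident weights are all zero, and isolated nodes,
#' have local entropy 0.
#'
#' @param net a \code{\link{build_sample_network}} result.
#' @return Named numeric vector of local entropies (nats), one per node.
#' @export
local_entropy <- function(net) {
  stopifnot(inherits(net, "sample_network"))
  g <- net$graph
  n <- vcount(g)
  el <- as_edgelist(g, names = FALSE)
  w <- E(g)$weight
  S <- numeric(n)
  sw <- numeric(n)
  sw_acc <- tapply(c(w, w), c(el[, 1], el[, 2]), sum)
  sw[as.integer(names(sw_acc))] <- sw_acc
  # -sum p log p accumulated edge-wise: each edge contributes to both ends
  idx <- c(el[, 1], el[, 2])
  ww <- c(w, w)
  pos <- ww > 0 & sw[idx] > 0
  p <- ww[pos] / sw[idx][pos]
  contrib <- tapply(-p * log(p), idx[pos], sum)
  S[as.integer(names(contrib))] <- contrib
  names(S) <- V(g)$name
  S
}

#' Entropy table for a cohort of samples
#'
#' Builds each sample's network, fits its ensemble, and collects global
#' entropies (raw and per-node-normalised) plus the node-by-sample local
#' entropy matrix.  Nodes absent from a sample's network (zero expression)
#' are NA in that column.
#'
#' @param cohort an \code{\link{expression_cohort}}.
#' @param scaffold scaffold \code{igraph}.
#' @param fit_global also fit the ensemble for global entropy (set FALSE to
#'   compute only local entropies, which is much faster).
#' @param tol,max_iter passed to \code{\link{fit_ensemble}}.
#'
#' @return A list of class \code{"entropy_table"}: \code{samples} (data frame
#'   with sample, group, n_nodes, n_edges, entropy_raw, entropy_per_node) and
#'   \code{local} (genes x samples matrix).
#' @export
cohort_entropy <- function(cohort, scaffold, fit_global = TRUE,
                           tol = 1e-8, max_iter = 10000L) {
  stopifnot(inherits(cohort, "expr_cohort"))
  ids <- colnames(cohort$values)
  genes <- intersect(rownames(cohort$values), V(scaffold)$name)
  local <- matrix(NA_real_, length(genes), length(ids),
                  dimnames = list(genes, ids))
  samples <- data.frame(sample = ids,
                        group = unname(cohort$groups[ids]),
                        n_nodes = NA_integer_, n_edges = NA_integer_,
                        entropy_raw = NA_real_, entropy_per_node = NA_real_,
                        stringsAsFactors = FALSE)
  for (j in seq_along(ids)) {
    net <- build_sample_network(cohort, ids[j], scaffold)
    samples$n_nodes[j] <- vcount(net$graph)
    samples$n_edges[j] <- ecount(net$graph)
    if (fit_global) {
      model <- fit_ensemble(net, bin_weights(net), tol = tol,
                            max_iter = max_iter)
      ge <- global_entropy(model)
      samples$entropy_raw[j] <- ge$raw
      samples$entropy_per_node[j] <- ge$per_node
    }
    le <- local_entropy(net)
    local[match(names(le), genes), j] <- le
  }
  structure(list(samples = samples, local = local), class = "entropy_table")
}

#' @export
print.entropy_table <- function(x, ...) {
  cat(sprintf("entropy_table: %d samples, %d genes\n",
              nrow(x$samples), nrow(x$local)))
  invisible(x)
}

#' Differential local entropy between two age groups
#'
#' Per gene, a two-sided Wilcoxon rank-sum test compares local entropies of
#' the young-group samples against the old-group samples.  The exact null is
#' used for combined sample sizes up to 20 without ties; larger or tied
#' comparisons use the normal approximation with continuity correction.
#' P-values are Benjamini-Hochberg adjusted across all tested genes, and a
#' gene is called significant when its q-value is below
#' \code{config$fdr_threshold} \emph{and} the absolute difference in group
#' location (median by default) exceeds \code{config$median_shift_threshold}.
#'
#' Genes absent from every sample of either side are dropped (counted in the
#' \code{n_dropped} attribute).
#'
#' @param table an \code{\link{cohort_entropy}} result.
#' @param young_groups,old_groups group labels defining the two sides.
#' @param config an \code{\link{run_config}}.
#'
#' @return Data frame with one row per tested gene: location (median or mean)
#'   per side, the shift, Wilcoxon statistic, p, q, and \code{significant}.
#' @export
differential_entropy <- function(table, young_groups, old_groups,
                                 config = run_config()) {
  stopifnot(inherits(table, "entropy_table"))
  young <- table$samples$sample[table$samples$group %in% young_groups]
  old <- table$samples$sample[table$samples$group %in% old_groups]
  if (length(young) < 2L || length(old) < 2L)
    stop("need at least 2 samples per side (young: ", length(young),
         ", old: ", length(old), ")")
  locfun <- if (config$location_stat == "median") median else mean
  L <- table$local
  genes <- rownames(L)
  keep <- rowSums(!is.na(L[, young, drop = FALSE])) >= 1 &
    rowSums(!is.na(L[, old, drop = FALSE])) >= 1
  n_dropped <- sum(!keep)
  genes <- genes[keep]
  res <- data.frame(gene = genes,
                    young = NA_real_, old = NA_real_, shift = NA_real_,
                    W = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    a <- L[genes[i], young]; a <- a[!is.na(a)]
    b <- L[genes[i], old]; b <- b[!is.na(b)]
    res$young[i] <- locfun(a)
    res$old[i] <- locfun(b)
    res$shift[i] <- res$old[i] - res$young[i]
    if (length(unique(c(a, b))) == 1L) {
      # degenerate: identical constant entropies on both sides
      res$W[i] <- length(a) * length(b) / 2
      res$p[i] <- 1
    } else {
      exact <- (length(a) + length(b) <= 20L) &&
        !any(duplicated(c(a, b)))
      wt <- suppressWarnings(wilcox.test(b, a, exact = exact, correct = TRUE))
      res$W[i] <- unname(wt$statistic)
      res$p[i] <- if (is.na(wt$p.value)) 1 else wt$p.value
    }
  }
  res$q <- p.adjust(res$p, method = "BH")
  res$significant <- res$q < config$fdr_threshold &
    abs(res$shift) > config$median_shift_threshold
  attr(res, "n_dropped") <- n_dropped
  res
}
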