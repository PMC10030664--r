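# Network proximity between condition gene sets ---------------------------

#' Mean closest shortest-path distance between two gene sets
#'
#' \deqn{d_{AB} = \frac{1}{\|A\|+\|B\|}\left(\sum_{a \in A} \min_{b \in B} d(a,b)
#'   + \sum_{b \in B} \min_{a \in A} d(a,b)\right)}
#' with unweighted (hop-count) shortest-path distances on the scaffold.
#' Genes with no finite distance to the other set are excluded from both the
#' numerator and the denominator; their count is recorded in the
#' \code{n_unreachable} attribute.
#'
#' @param scaffold scaffold \code{igraph}.
#' @param A,B character vectors of scaffold gene symbols (e.g.
#'   \code{\link{gene_set}}s).
#' @return The distance (symmetric in A and B; zero when A equals B), with
#'   attribute \code{n_unreachable}.
#' @export
closest_distance <- function(scaffold, A, B) {
  A <- as.character(A); B <- as.character(B)
  stopifnot(length(A) > 0, length(B) > 0)
  D <- distances(scaffold, v = A, to = B, weights = NA)
  minA <- apply(D, 1, min)  # per a in A
  minB <- apply(D, 2, min)  # per b in B
  vals <- c(minA, minB)
  unreachable <- !is.finite(vals)
  if (all(unreachable)) stop("no finite distance between the two gene sets")
  d <- sum(vals[!unreachable]) / sum(!unreachable)
  attr(d, "n_unreachable") <- sum(unreachable)
  d
}

#' Logarithmic degree bins for null sampling
#'
#' Scaffold nodes are binned by degree into base-2 logarithmic bins; bins are
#' merged upward (lowest first) until each holds at least \code{min_bin_size}
#' nodes (or the whole graph, if smaller).
#'
#' @param scaffold scaffold \code{igraph}.
#' @param min_bin_size merge floor.
#' @return A list of class \code{"degree_bins"}: \code{bin_of} (named bin
#'   index per node) and \code{members} (list of node-name vectors).
#' @export
degree_bins <- function(scaffold, min_bin_size = 100L) {
  deg <- degree(scaffold)
  raw <- floor(log2(pmax(deg, 1)))
  lev <- sort(unique(raw))
  # merge upward until every bin reaches the floor
  groups <- as.list(lev)
  repeat {
    counts <- vapply(groups, function(g) sum(raw %in% g), 0L)
    small <- which(counts < min_bin_size)
    if (length(small) == 0L || length(groups) == 1L) break
    i <- small[1]
    j <- if (i < length(groups)) i + 1L else i - 1L
    groups[[j]] <- c(groups[[j]], groups[[i]])
    groups[[i]] <- NULL
  }
  bin_of <- integer(length(deg))
  for (b in seq_along(groups)) bin_of[raw %in% groups[[b]]] <- b
  names(bin_of) <- V(scaffold)$name
  members <- split(names(bin_of), bin_of)
  structure(list(bin_of = bin_of, members = members), class = "degree_bins")
}

#' Degree-matched random gene set
#'
#' Draws one random scaffold node per template gene from the template gene's
#' merged degree bin, without replacement within bins, so the sampled set
#' reproduces the template's degree-bin histogram exactly.
#'
#' @param scaffold scaffold \code{igraph}.
#' @param template character vector of scaffold gene symbols.
#' @param bins optional precomputed \code{\link{degree_bins}}.
#' @return Character vector of sampled node names, same length as
#'   \code{template}, no duplicates.
#' @export
degree_matched_sample <- function(scaffold, template, bins = NULL) {
  if (is.null(bins)) bins <- degree_bins(scaffold)
  template <- as.character(template)
  tb <- bins$bin_of[template]
  if (any(is.na(tb))) stop("template gene off the scaffold: ",
                           template[is.na(tb)][1])
  need <- table(tb)
  out <- character(0)
  for (b in names(need)) {
    pool <- bins$members[[b]]
    if (length(pool) < need[[b]])
      stop("degree bin ", b, " holds ", length(pool),
           " nodes but ", need[[b]], " draws requested")
    out <- c(out, sample(pool, need[[b]]))
  }
  out
}

#' Proximity Z-score with a degree-matched permutation null
#'
#' Computes the observed closest distance between A and B, then
#' \code{n_permutations} independent distances between degree-matched
#' resamples of both sets.  Z = (d_AB - mean) / sd of the null; the empirical
#' p-value is (number of null distances <= observed + 1) / (n + 1).
#'
#' @param scaffold scaffold \code{igraph}.
#' @param A,B \code{\link{gene_set}}s (or character vectors of scaffold genes).
#' @param config an \code{\link{run_config}}; uses \code{n_permutations},
#'   \code{z_threshold}.
#' @param bins optional precomputed \code{\link{degree_bins}}.
#'
#' @return A list of class \code{"proximity_result"}: names, n_mapped per
#'   side, \code{d}, null mean \code{d_m} and sd \code{sigma_m}, \code{z}
#'   (NA when sigma_m is 0), \code{p_empirical}, \code{n_unreachable}.
#' @export
proximity_z <- function(scaffold, A, B, config = run_config(), bins = NULL) {
  if (is.null(bins)) bins <- degree_bins(scaffold)
  d_obs <- closest_distance(scaffold, A, B)
  nulls <- numeric(config$n_permutations)
  for (i in seq_len(config$n_permutations)) {
    As <- degree_matched_sample(scaffold, A, bins)
    Bs <- degree_matched_sample(scaffold, B, bins)
    nulls[i] <- closest_distance(scaffold, As, Bs)
  }
  d_m <- mean(nulls); sigma_m <- sd(nulls)
  z <- if (sigma_m > 0) (as.numeric(d_obs) - d_m) / sigma_m else NA_real_
  structure(list(name_A = attr(A, "name") %||% "A",
                 name_B = attr(B, "name") %||% "B",
                 n_A = length(A), n_B = length(B),
                 d = as.numeric(d_obs), d_m = d_m, sigma_m = sigma_m,
                 z = z,
                 p_empirical = (sum(nulls <= as.numeric(d_obs)) + 1) /
                   (config$n_permutations + 1),
                 n_unreachable = attr(d_obs, "n_unreachable")),
            class = "proximity_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.proximity_result <- function(x, ...) {
  cat(sprintf("proximity %s ~ %s: d = %.3f, null %.3f +/- %.3f, Z = %.2f, p = %.4f\n",
              x$name_A, x$name_B, x$d, x$d_m, x$sigma_m, x$z, x$p_empirical))
  invisible(x)
}

#' Genes on shortest paths between two condition sets
#'
#' For every pair (a in A, b in B) with finite distance, collects all nodes
#' lying on any shortest a-b path (a node v is on one exactly when
#' d(a,v) + d(v,b) = d(a,b)).  Roles: \code{common} for genes in both sets,
#' otherwise \code{endpoint_A} / \code{endpoint_B} for members of one set,
#' and \code{intermediate} for pure path nodes.
#'
#' @param scaffold scaffold \code{igraph}.
#' @param A,B character vectors of scaffold gene symbols.
#' @return Data frame (gene, role), ordered by role then symbol.
#' @export
proximity_genes <- function(scaffold, A, B) {
  A <- as.character(A); B <- as.character(B)
  DA <- distances(scaffold, v = A, weights = NA)
  DB <- distances(scaffold, v = B, weights = NA)
  nodes <- colnames(DA)
  on_path <- logical(length(nodes))
  for (i in seq_along(A)) {
    for (j in seq_along(B)) {
      dab <- DA[i, B[j]]
      if (!is.finite(dab)) next
      on_path <- on_path | (DA[i, ] + DB[j, ] == dab)
    }
  }
  genes <- nodes[on_path]
  if (length(genes) == 0L)
    return(data.frame(gene = character(0), role = character(0),
                      stringsAsFactors = FALSE))
  role <- ifelse(genes %in% A & genes %in% B, "common",
                 ifelse(genes %in% A, "endpoint_A",
                        ifelse(genes %in% B, "endpoint_B", "intermediate")))
  out <- data.frame(gene = genes, role = role, stringsAsFactors = FALSE)
  out[order(out$role, out$gene), , drop = FALSE]
}

#' Proximity of one reference set against many conditions
#'
#' Runs \code{\link{proximity_z}} for each (reference, condition) pair,
#' applies Benjamini-Hochberg correction to the empirical p-values across
#' the tested pairs, and flags pairs with Z below \code{config$z_threshold}
#' and q below \code{config$fdr_threshold} as significantly proximal.
#'
#' @param scaffold scaffold \code{igraph}.
#' @param conditions named list of \code{\link{gene_set}}s.
#' @param reference the reference \code{\link{gene_set}} (e.g. ageing DEGs).
#' @param config an \code{\link{run_config}}.
#' @return Data frame, one row per condition: condition, n_genes, d, d_m,
#'   sigma_m, z, p_empirical, q, significant.
#' @export
pairwise_proximity_matrix <- function(scaffold, conditions, reference,
                                      config = run_config()) {
  if (length(conditions) == 0L)
    return(data.frame(condition = character(0), n_genes = integer(0),
                      d = numeric(0), d_m = numeric(0), sigma_m = numeric(0),
                      z = numeric(0), p_empirical = numeric(0),
                      q = numeric(0), significant = logical(0),
                      stringsAsFactors = FALSE))
  bins <- degree_bins(scaffold)
  rows <- lapply(conditions, function(cond)
    proximity_z(scaffold, reference, cond, config, bins))
  nm <- names(conditions)
  if (is.null(nm)) nm <- vapply(rows, `[[`, "", "name_B")
  df <- data.frame(condition = nm,
                   n_genes = vapply(rows, `[[`, 0L, "n_B"),
                   d = vapply(rows, `[[`, 0, "d"),
                   d_m = vapply(rows, `[[`, 0, "d_m"),
                   sigma_m = vapply(rows, `[[`, 0, "sigma_m"),
                   z = vapply(rows, function(r) r$z %||% NA_real_, 0),
                   p_empirical = vapply(rows, `[[`, 0, "p_empirical"),
                   row.names = NULL, stringsAsFactors = FALSE)
  df$q <- p.adjust(df$p_empirical, method = "BH")
  df$significant <- !is.na(df$z) & df$z < config$z_threshold &
    df$q < config$fdr_threshold
  df
}
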