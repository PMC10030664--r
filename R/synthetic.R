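# Synthetic benchmark generators ------------------------------------------
#
# The generators produce a scaffold, an age-ordered expression cohort and
# condition gene sets with planted, recoverable ground truth.  The design
# targets three phenotypes of the ageing-liver analysis while keeping the
# planted signals identifiable:
#
#  * a scale-free backbone plus hub-and-spoke "satellite complexes" whose
#    spoke partners interact only with their core -- a recognised feature of
#    high-confidence PPI networks.  Degree-1 spokes are entropy-inert (a
#    single-edge node always has local entropy 0), so perturbing a
#    satellite's spoke layout shifts only the core's local entropy;
#  * group-proportional scaling of both between-gene expression contrast and
#    within-group noise, so the local-entropy distribution of unperturbed
#    genes is exactly age-invariant (a pure scale family) while the global
#    edge-weight histogram, anchored by a fixed-expression reference triad,
#    spreads with age and drives the global entropy trend;
#  * planted differential expression as mean shifts in the oldest groups.

#' Generate a synthetic PPI scaffold
#'
#' A preferential-attachment (Barabasi-Albert) backbone with optional
#' satellite complexes (cores of moderate backbone degree, each with
#' degree-1 spoke partners), an optional fixed-expression reference triad
#' attached to the main hub, and optional planted cliques for module
#' detection benchmarks.
#'
#' @param n_genes total node count (backbone + spokes + triad).
#' @param m preferential-attachment edges per new backbone node.
#' @param n_satellites number of satellite complexes (0 for a plain
#'   backbone).
#' @param leaves_per_satellite spoke partners per satellite core.
#' @param reference_triad attach a 3-gene reference triangle to the main hub.
#' @param planted_clique_sizes integer vector; for each entry, edges are
#'   added among that many randomly chosen backbone nodes to complete a
#'   clique.
#' @param seed RNG seed.
#'
#' @return An undirected simple \code{igraph} with vertex attributes
#'   \code{role} ("core", "leaf", "reference") and \code{satellite}
#'   (complex id or NA), plus graph attributes recording the construction
#'   (including \code{planted_cliques}, a list of member-name vectors).
#' @export
make_scaffold <- function(n_genes = 500L, m = 3L, n_satellites = 55L,
                          leaves_per_satellite = 5L, reference_triad = TRUE,
                          planted_clique_sizes = NULL, seed = 1L) {
  stopifnot(n_genes > m, m >= 1)
  set.seed(seed)
  n_leaf <- n_satellites * leaves_per_satellite
  n_ref <- if (reference_triad) 3L else 0L
  n_core <- n_genes - n_leaf - n_ref
  stopifnot(n_core > m + 1L)
  g <- sample_pa(n_core, m = m, directed = FALSE)
  role <- rep("core", n_core)
  satellite <- rep(NA_integer_, n_core)
  if (n_satellites > 0L) {
    deg <- degree(g)
    cand <- which(deg >= m & deg <= m + 2L)
    if (length(cand) < n_satellites)
      stop("backbone too small for ", n_satellites, " satellite cores")
    cores <- sort(sample(cand, n_satellites))
    satellite[cores] <- seq_len(n_satellites)
    idx <- n_core
    for (ci in seq_len(n_satellites)) {
      g <- add_vertices(g, leaves_per_satellite)
      g <- add_edges(g, as.vector(rbind(idx + seq_len(leaves_per_satellite),
                                        cores[ci])))
      role <- c(role, rep("leaf", leaves_per_satellite))
      satellite <- c(satellite, rep(ci, leaves_per_satellite))
      idx <- idx + leaves_per_satellite
    }
  }
  planted <- list()
  if (!is.null(planted_clique_sizes)) {
    avail <- which(role == "core" & is.na(satellite))
    for (sz in planted_clique_sizes) {
      pick <- sample(avail, sz)
      avail <- setdiff(avail, pick)
      pairs <- combn(pick, 2)
      g <- add_edges(g, as.vector(pairs))
      planted[[length(planted) + 1L]] <- pick
    }
    g <- simplify(g)
  }
  if (reference_triad) {
    hub <- which.max(degree(g))
    nv <- vcount(g)
    g <- add_vertices(g, 3L)
    g <- add_edges(g, c(nv + 1L, nv + 2L, nv + 2L, nv + 3L,
                        nv + 1L, nv + 3L, nv + 1L, hub))
    role <- c(role, rep("reference", 3L))
    satellite <- c(satellite, rep(NA_integer_, 3L))
  }
  V(g)$name <- sprintf("G%04d", seq_len(vcount(g)))
  V(g)$role <- role
  V(g)$satellite <- satellite
  g$n_core <- n_core
  g$m <- m
  g$planted_cliques <- lapply(planted, function(p) V(g)$name[p])
  g$backbone_edges <- m * (n_core - m) + choose(m, 2)
  g
}

#' Generate an age-ordered expression cohort with planted truth
#'
#' Expression for sample s in group g is
#' \code{b0 + amp_g * delta + Normal(0, noise_scale[g])} with
#' \code{amp_g = noise_scale[g] / noise_scale[1]}: contrast and noise grow
#' proportionally, so the incident-weight distribution of every unperturbed
#' gene is a pure scale family across ages and its local entropy
#' distribution is age-invariant.  The reference triad keeps fixed values
#' spanning the dynamic range, anchoring the weight-histogram bins so the
#' global ensemble entropy rises with the noise scale.
#'
#' Satellite spokes start from an ordered layout (one dominant "specific
#' interaction" at distance \code{strong_distance}, the rest at
#' \code{leaf_distance_range}); in the samples of \code{shift_groups} the
#' spokes of the planted cores are re-drawn at a common distance (entropy
#' rises to ~log degree).  Planted DEGs get a mean shift of
#' \code{effect * noise_scale[g]} in the \code{shift_groups}.
#'
#' @param scaffold a \code{\link{make_scaffold}} result.
#' @param groups ordered group labels (ages in months).
#' @param n_per_group replicate samples per group.
#' @param noise_scale non-decreasing per-group noise sd (default: 0.1 to 0.5,
#'   evenly spaced).
#' @param entropy_shift_genes number of planted entropy-shift genes (satellite
#'   cores; at most the number of satellites).
#' @param deg_genes number of planted differentially expressed genes.
#' @param effect DEG shift in units of the group noise sd.
#' @param shift_groups groups whose samples carry the planted perturbations
#'   (default: the last two).
#' @param b0 baseline expression level (VST-like scale).
#' @param delta_sd sd of the per-gene baseline offsets.
#' @param strong_distance baseline offset distance of each satellite's
#'   dominant spoke.
#' @param leaf_distance_range range of the remaining spoke distances.
#' @param equalise_jitter relative jitter of the equalised spoke distances.
#' @param reference_values fixed expression of the reference triad.
#' @param seed RNG seed.
#'
#' @return A list: \code{cohort} (an \code{\link{expression_cohort}}) and
#'   \code{truth} (class \code{"synthetic_truth"}: planted entropy-shift
#'   genes, DEG genes and signs, satellite/reference membership, and all
#'   generator parameters).
#' @export
make_cohort <- function(scaffold,
                        groups = c(3, 6, 9, 12, 15, 18, 21, 24, 27),
                        n_per_group = 4L,
                        noise_scale = NULL,
                        entropy_shift_genes = 50L,
                        deg_genes = 50L,
                        effect = 3,
                        shift_groups = NULL,
                        b0 = 10,
                        delta_sd = 0.3,
                        strong_distance = 2.0,
                        leaf_distance_range = c(0.4, 0.7),
                        equalise_jitter = 0.05,
                        reference_values = c(25, 15, 3),
                        seed = 1L) {
  set.seed(seed)
  if (is.null(noise_scale))
    noise_scale <- seq(0.1, 0.5, length.out = length(groups))
  stopifnot(length(noise_scale) == length(groups),
            all(diff(noise_scale) >= 0))
  if (is.null(shift_groups)) shift_groups <- utils::tail(groups, 2)
  nodes <- V(scaffold)$name
  N <- length(nodes)
  role <- V(scaffold)$role %||% rep("core", N)
  sat <- V(scaffold)$satellite %||% rep(NA_integer_, N)
  sat_cores <- which(role == "core" & !is.na(sat))
  leaf_of <- lapply(seq_along(sat_cores), function(ci)
    which(role == "leaf" & sat == sat[sat_cores[ci]]))
  ref <- which(role == "reference")
  stopifnot(entropy_shift_genes <= length(sat_cores))
  nbl <- lapply(seq_len(N), function(v) as.integer(neighbors(scaffold, v)))

  delta <- rnorm(N, 0, delta_sd)
  for (ci in seq_along(sat_cores)) {
    lv <- leaf_of[[ci]]
    dist <- c(strong_distance,
              runif(length(lv) - 1L, leaf_distance_range[1],
                    leaf_distance_range[2]))
    sgn <- sample(c(-1, 1), length(lv), replace = TRUE)
    delta[lv] <- delta[sat_cores[ci]] + sgn * dist
  }
  planted <- if (entropy_shift_genes > 0L)
    sort(sample(sat_cores, entropy_shift_genes)) else integer(0)
  deg_pool <- which(role == "core" & is.na(sat))
  deg_pool <- setdiff(deg_pool, ref)
  stopifnot(deg_genes <= length(deg_pool))
  degs <- if (deg_genes > 0L) sort(sample(deg_pool, deg_genes)) else integer(0)
  deg_sign <- sample(c(-1, 1), length(degs), replace = TRUE)

  s1 <- noise_scale[1]
  n_samples <- length(groups) * n_per_group
  E <- matrix(0, N, n_samples, dimnames = list(nodes, NULL))
  grp <- rep(groups, each = n_per_group)
  ids <- sprintf("S%02d_%sm", seq_len(n_samples), grp)
  colnames(E) <- ids
  pli <- match(planted, sat_cores)
  for (smp in seq_len(n_samples)) {
    gi <- match(grp[smp], groups)
    sc <- noise_scale[gi]
    amp <- if (s1 > 0) sc / s1 else 1
    e <- b0 + amp * delta + rnorm(N, 0, sc)
    if (grp[smp] %in% shift_groups) {
      if (length(degs)) e[degs] <- e[degs] + deg_sign * effect * sc
      for (ii in seq_along(planted)) {
        v <- planted[ii]
        lv <- leaf_of[[pli[ii]]]
        d <- mean(abs(e[nbl[[v]]] - e[v]))
        sgn <- sample(c(-1, 1), length(lv), replace = TRUE)
        e[lv] <- e[v] + sgn * d *
          (1 + rnorm(length(lv), 0, equalise_jitter))
      }
    }
    if (length(ref)) e[ref] <- reference_values[seq_along(ref)]
    E[, smp] <- pmax(e, 0.01)
  }
  cohort <- expression_cohort(E, setNames(grp, ids))
  truth <- structure(list(
    entropy_shift_genes = nodes[planted],
    deg_genes = nodes[degs],
    deg_signs = setNames(deg_sign, nodes[degs]),
    satellite_cores = nodes[sat_cores],
    reference_genes = nodes[ref],
    shift_groups = shift_groups,
    groups = groups,
    n_per_group = n_per_group,
    noise_scale = noise_scale,
    effect = effect,
    b0 = b0, delta_sd = delta_sd,
    strong_distance = strong_distance,
    leaf_distance_range = leaf_distance_range,
    equalise_jitter = equalise_jitter,
    reference_values = reference_values,
    seed = seed), class = "synthetic_truth")
  list(cohort = cohort, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth: %d entropy-shift genes, %d DEGs, groups %s\n",
              length(x$entropy_shift_genes), length(x$deg_genes),
              paste(x$groups, collapse = ",")))
  invisible(x)
}

#' Generate condition gene sets with controlled proximity
#'
#' Draws a proximal set from the one-hop neighbourhood of the reference set
#' (the reference genes and their direct neighbours) and a distal set from
#' nodes at shortest-path distance of at least \code{min_distal_distance}
#' from every reference gene.  If that stratum is empty, the maximum
#' available distance stratum is used instead (recorded in the truth).
#'
#' @param scaffold scaffold \code{igraph}.
#' @param reference a \code{\link{gene_set}}.
#' @param proximal_size,distal_size sizes of the two sets.
#' @param min_distal_distance target minimum distance of the distal stratum.
#' @param seed RNG seed.
#' @return A list: \code{proximal}, \code{distal} (both
#'   \code{\link{gene_set}}s) and \code{truth} (strata sizes, realised
#'   distal distance).
#' @export
make_condition_sets <- function(scaffold, reference, proximal_size = 30L,
                                distal_size = 30L, min_distal_distance = 4,
                                seed = 1L) {
  set.seed(seed)
  ref <- as.character(reference)
  vids <- match(ref, V(scaffold)$name)
  hood <- union(ref,
                V(scaffold)$name[unique(unlist(adjacent_vertices(scaffold, vids)))])
  if (length(hood) < proximal_size)
    stop("one-hop neighbourhood (", length(hood),
         ") smaller than proximal_size")
  proximal <- sample(hood, proximal_size)
  mind <- apply(distances(scaffold, v = ref, weights = NA), 2, min)
  used_distance <- min_distal_distance
  stratum <- names(mind)[is.finite(mind) & mind >= used_distance]
  while (length(stratum) < distal_size && used_distance > 1) {
    used_distance <- used_distance - 1
    stratum <- names(mind)[is.finite(mind) & mind >= used_distance]
  }
  if (length(stratum) < distal_size)
    stop("cannot find ", distal_size, " nodes away from the reference set")
  distal <- sample(stratum, distal_size)
  list(proximal = gene_set(proximal, scaffold, "proximal"),
       distal = gene_set(distal, scaffold, "distal"),
       truth = structure(list(
         proximal_pool = length(hood),
         distal_pool = length(stratum),
         requested_distal_distance = min_distal_distance,
         realised_distal_distance = used_distance,
         seed = seed), class = "synthetic_truth"))
}
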