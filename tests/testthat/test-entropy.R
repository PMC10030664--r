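make_net_with_weights <- function(g, weights) {
  as_sample_network(g, weights)
}

test_that("saturated ensembles are deterministic with zero entropy", {
  # K4, all weights equal: every pair must carry an edge, S = 0
  g <- complete_named(4)
  net <- make_net_with_weights(g, rep(1, 6))
  model <- fit_ensemble(net, bin_weights(net))
  expect_true(model$saturated)
  expect_equal(global_entropy(model)$raw, 0)

  # a single linked pair is also forced
  g2 <- named_graph("a", "b")
  net2 <- make_net_with_weights(g2, 0.5)
  model2 <- fit_ensemble(net2, bin_weights(net2))
  expect_true(model2$saturated)
  expect_equal(global_entropy(model2)$raw, 0)
})

test_that("fitted ensembles reproduce degrees and bin counts within tolerance", {
  set.seed(21)
  for (rep in 1:5) {
    g <- random_fit_graph(sample(5:8, 1))
    w <- runif(ecount(g))
    net <- make_net_with_weights(g, w)
    bw <- bin_weights(net)
    model <- fit_ensemble(net, bw, tol = 1e-8)
    expect_lte(model$residual, 1e-8)
    p <- link_probabilities(model)
    expect_equal(unname(rowSums(p)), unname(degree(g)), tolerance = 1e-7)
    # expected bin counts are w_bin * expected edges
    expect_equal(model$w_bin * sum(p[upper.tri(p)]),
                 bw$counts, tolerance = 1e-6, ignore_attr = TRUE)
    # pair probabilities complete: p0 + sum_q p_q = 1 by construction
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("ensemble entropy matches direct constrained maximisation on small graphs", {
  set.seed(5)
  for (rep in 1:3) {
    g <- random_fit_graph(6)
    w <- runif(ecount(g))
    net <- make_net_with_weights(g, w)
    bw <- bin_weights(net)
    # keep the oracle problem small: collapse to at most 2 occupied bins
    bins <- ifelse(bw$bin <= stats::median(bw$bin), 1L, 2L)
    counts <- tabulate(bins, 2L)
    bw2 <- structure(list(n_bins = 2L, breaks = c(0, 0.5, 1),
                          counts = counts, bin = bins),
                     class = "weight_binning")
    model <- fit_ensemble(net, bw2)
    S <- global_entropy(model)$raw
    oracle <- oracle_ensemble_entropy(unname(degree(g)), counts)
    expect_lt(oracle$violation, 1e-6)
    expect_equal(S, oracle$entropy, tolerance = 1e-6)
  }
})

test_that("ensemble fit rejects degenerate inputs", {
  g <- star_named(4)  # centre has full degree: no finite solution
  net <- make_net_with_weights(g, runif(4))
  expect_error(fit_ensemble(net, bin_weights(net)), "full degree")
})

test_that("local entropy follows the normalised incident-weight distribution", {
  # four equal-weight edges: uniform maximum ln 4
  g <- star_named(4)
  le <- local_entropy(make_net_with_weights(g, rep(2, 4)))
  expect_equal(unname(le["center"]), log(4))
  # a single edge gives zero
  expect_equal(unname(le[2]), 0)

  # incident weights (1, 1, 2): p = (0.25, 0.25, 0.5)
  g2 <- star_named(3)
  le2 <- local_entropy(make_net_with_weights(g2, c(1, 1, 2)))
  expect_equal(unname(le2["center"]),
               -sum(c(.25, .25, .5) * log(c(.25, .25, .5))))

  # zero-weight edges contribute nothing; all-zero and isolated nodes get 0
  g3 <- igraph::add_vertices(star_named(3), 1, name = "iso")
  le3 <- local_entropy(make_net_with_weights(g3, c(0, 0, 0)))
  expect_equal(unname(le3[c("center", "iso")]), c(0, 0))

  # bounds: 0 <= S_i <= ln(degree)
  set.seed(9)
  g4 <- er_named(25, 0.25)
  le4 <- local_entropy(make_net_with_weights(g4, runif(ecount(g4))))
  expect_true(all(le4 >= 0))
  expect_true(all(le4 <= log(pmax(degree(g4), 2)) + 1e-12))
})

test_that("differential entropy applies the exact Wilcoxon test and the shift filter", {
  mk_table <- function(local, groups) {
    ids <- colnames(local)
    structure(list(samples = data.frame(sample = ids, group = groups,
                                        n_nodes = NA, n_edges = NA,
                                        entropy_raw = NA,
                                        entropy_per_node = NA),
                   local = local),
              class = "entropy_table")
  }
  # identical values both sides: p = 1, not significant
  L <- matrix(rep(c(1, 2), each = 8), 2, 8, byrow = TRUE,
              dimnames = list(c("g1", "g2"), paste0("S", 1:8)))
  tab <- mk_table(L, rep(c(3, 27), each = 4))
  res <- differential_entropy(tab, 3, 27)
  expect_true(all(res$p == 1))
  expect_false(any(res$significant))

  # fully separated 4 vs 4: exact two-sided p = 2/70
  L2 <- rbind(g1 = c(1, 2, 3, 4, 11, 12, 13, 14))
  colnames(L2) <- paste0("S", 1:8)
  res2 <- differential_entropy(mk_table(L2, rep(c(3, 27), each = 4)), 3, 27)
  expect_equal(res2$p, 2 / 70)
  expect_equal(res2$p, oracle_wilcoxon_p(L2[1, 1:4], L2[1, 5:8]))

  # significant shift must exceed the 0.03 nats median filter
  base <- c(0.500, 0.502, 0.504, 0.506)
  L3 <- rbind(small = c(base, base + 0.02), big = c(base, base + 0.2))
  colnames(L3) <- paste0("S", 1:8)
  res3 <- differential_entropy(mk_table(L3, rep(c(3, 27), each = 4)), 3, 27)
  expect_false(res3$significant[res3$gene == "small"])
  expect_true(res3$significant[res3$gene == "big"])

  # fewer than two samples per side is an error
  expect_error(differential_entropy(mk_table(L, c(3, rep(27, 7))), 3, 27),
               "at least 2 samples")
})
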