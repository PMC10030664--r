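test_that("scaffold generation matches its closed-form edge count and is reproducible", {
  g <- make_scaffold(500, m = 3, n_satellites = 0, reference_triad = FALSE,
                     seed = 5)
  expect_equal(vcount(g), 500L)
  expect_equal(ecount(g), 3 * (500 - 3) + choose(3, 2))
  expect_true(igraph::is_connected(g))
  expect_true(igraph::is_simple(g))

  g2 <- make_scaffold(500, m = 3, n_satellites = 0, reference_triad = FALSE,
                      seed = 5)
  expect_identical(as_edgelist(g), as_edgelist(g2))

  # satellite + triad bookkeeping: total node count and roles add up
  g3 <- make_scaffold(500, seed = 5)
  expect_equal(vcount(g3), 500L)
  expect_equal(sum(V(g3)$role == "leaf"), 55L * 5L)
  expect_equal(sum(V(g3)$role == "reference"), 3L)
  expect_true(all(degree(g3)[V(g3)$role == "leaf"] == 1))

  # planted cliques are present as complete subgraphs
  g4 <- make_scaffold(200, m = 2, n_satellites = 0, reference_triad = FALSE,
                      planted_clique_sizes = c(6, 5), seed = 9)
  for (cl in g4$planted_cliques) {
    sub <- igraph::induced_subgraph(g4, cl)
    expect_equal(ecount(sub), choose(length(cl), 2))
  }
})

test_that("cohort generation is deterministic and degenerates correctly at zero noise", {
  g <- make_scaffold(200, m = 2, n_satellites = 10, leaves_per_satellite = 4,
                     seed = 3)
  sim1 <- make_cohort(g, groups = c(3, 9, 27), n_per_group = 3,
                      entropy_shift_genes = 8, deg_genes = 20, seed = 13)
  sim2 <- make_cohort(g, groups = c(3, 9, 27), n_per_group = 3,
                      entropy_shift_genes = 8, deg_genes = 20, seed = 13)
  expect_identical(sim1$cohort$values, sim2$cohort$values)
  expect_identical(sim1$truth$entropy_shift_genes, sim2$truth$entropy_shift_genes)

  # zero noise, no planted mechanisms: all samples identical, equal entropies
  sim0 <- make_cohort(g, groups = c(3, 9, 27), n_per_group = 2,
                      noise_scale = c(0, 0, 0), entropy_shift_genes = 0,
                      deg_genes = 0, seed = 13)
  vals <- sim0$cohort$values
  expect_true(all(vals == vals[, 1]))
  ent <- cohort_entropy(sim0$cohort, g, fit_global = FALSE)
  expect_true(all(apply(ent$local, 1, function(r) length(unique(r)) == 1)))
})

test_that("every planted identifier resolves in the generated data", {
  g <- make_scaffold(300, m = 3, n_satellites = 20, leaves_per_satellite = 4,
                     seed = 7)
  sim <- make_cohort(g, entropy_shift_genes = 15, deg_genes = 20, seed = 7)
  tr <- sim$truth
  expect_true(all(tr$entropy_shift_genes %in% rownames(sim$cohort$values)))
  expect_true(all(tr$entropy_shift_genes %in% V(g)$name))
  expect_true(all(tr$deg_genes %in% V(g)$name))
  expect_true(all(tr$reference_genes %in% V(g)$name))
  # planted mechanisms act on disjoint gene sets
  expect_length(intersect(tr$entropy_shift_genes, tr$deg_genes), 0)
  expect_length(intersect(tr$deg_genes, tr$reference_genes), 0)
})

test_that("condition sets respect their planted proximity strata", {
  g <- make_scaffold(400, m = 3, n_satellites = 0, reference_triad = FALSE,
                     seed = 11)
  set.seed(11)
  ref <- gene_set(sample(V(g)$name, 30), g, "ref")
  sets <- make_condition_sets(g, ref, proximal_size = 20, distal_size = 20,
                              seed = 21)
  # every proximal gene sits within one hop of the reference set
  mind <- apply(igraph::distances(g, v = as.character(ref), weights = NA), 2, min)
  expect_true(all(mind[as.character(sets$proximal)] <= 1))
  expect_true(all(mind[as.character(sets$distal)] >=
                    sets$truth$realised_distal_distance))

  sets2 <- make_condition_sets(g, ref, proximal_size = 20, distal_size = 20,
                               seed = 21)
  expect_identical(as.character(sets$proximal), as.character(sets2$proximal))
  expect_identical(as.character(sets$distal), as.character(sets2$distal))
})

test_that("planted DEGs are recovered by the DE stand-in on a flat-noise cohort", {
  recovered <- logical(5)
  for (s in 1:5) {
    g <- make_scaffold(500, seed = 600 + s)
    sim <- make_cohort(g, noise_scale = rep(0.4, 9), deg_genes = 50,
                       entropy_shift_genes = 0, effect = 3, seed = 600 + s)
    de <- simple_de(sim$cohort, c(3, 6), c(24, 27), q_cutoff = 0.05)
    hits <- sum(attr(de, "selected") %in% sim$truth$deg_genes)
    recovered[s] <- hits >= 45
  }
  expect_gte(sum(recovered), 4L)
})
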