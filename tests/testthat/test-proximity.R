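test_that("closest distance matches hand-computed values and the direct oracle", {
  p5 <- path_named(5)
  expect_equal(as.numeric(closest_distance(p5, "n01", "n05")), 4)
  expect_equal(as.numeric(closest_distance(p5, c("n01", "n02"),
                                           c("n04", "n05"))), 2.5)
  expect_equal(as.numeric(closest_distance(p5, c("n01", "n03"),
                                           c("n01", "n03"))), 0)

  set.seed(29)
  for (rep in 1:20) {
    g <- er_named(8, 0.35)
    nm <- V(g)$name
    A <- sample(nm, sample(2:4, 1)); B <- sample(nm, sample(2:4, 1))
    d <- tryCatch(closest_distance(g, A, B), error = function(e) NULL)
    if (is.null(d)) next
    expect_equal(as.numeric(d), oracle_closest_distance(g, A, B))
    expect_equal(as.numeric(closest_distance(g, B, A)), as.numeric(d))
  }
})

test_that("distance is symmetric on many random set pairs and monotone under shared genes", {
  set.seed(37)
  g <- make_scaffold(150, m = 2, n_satellites = 0, reference_triad = FALSE,
                     seed = 37)
  nm <- V(g)$name
  for (rep in 1:200) {
    A <- sample(nm, 8); B <- sample(nm, 8)
    expect_equal(as.numeric(closest_distance(g, A, B)),
                 as.numeric(closest_distance(g, B, A)))
  }
  # adding to B a gene already in A can only decrease the distance
  for (rep in 1:20) {
    A <- sample(nm, 10); B <- sample(setdiff(nm, A), 10)
    d0 <- as.numeric(closest_distance(g, A, B))
    d1 <- as.numeric(closest_distance(g, A, c(B, A[1])))
    expect_lte(d1, d0 + 1e-12)
  }
})

test_that("unreachable genes are excluded and fully disconnected sets error", {
  g <- named_graph("a", "b", "c", "d")  # two components
  d <- closest_distance(g, c("a", "c"), "b")
  expect_equal(as.numeric(d), 1)  # c and its pairings excluded
  expect_equal(attr(d, "n_unreachable"), 1L)
  expect_error(closest_distance(g, "a", "d"), "no finite distance")
})

test_that("degree-matched sampling preserves the degree-bin histogram exactly", {
  set.seed(43)
  g <- make_scaffold(400, m = 3, n_satellites = 0, reference_triad = FALSE,
                     seed = 43)
  bins <- degree_bins(g, min_bin_size = 100)
  counts <- table(bins$bin_of)
  expect_true(all(counts >= 100 | length(counts) == 1))

  template <- sample(V(g)$name, 40)
  for (rep in 1:5) {
    s <- degree_matched_sample(g, template, bins)
    expect_length(s, 40)
    expect_equal(anyDuplicated(s), 0L)
    expect_equal(table(bins$bin_of[s]), table(bins$bin_of[template]))
  }

  # determinism under a fixed seed
  set.seed(7); s1 <- degree_matched_sample(g, template, bins)
  set.seed(7); s2 <- degree_matched_sample(g, template, bins)
  expect_identical(s1, s2)
})

test_that("proximity results are deterministic under a fixed seed", {
  set.seed(47)
  g <- make_scaffold(200, m = 3, n_satellites = 0, reference_triad = FALSE,
                     seed = 47)
  A <- gene_set(sample(V(g)$name, 15), g, "A")
  B <- gene_set(sample(V(g)$name, 15), g, "B")
  cfg <- run_config(n_permutations = 100)
  set.seed(11); r1 <- proximity_z(g, A, B, cfg)
  set.seed(11); r2 <- proximity_z(g, A, B, cfg)
  expect_identical(r1, r2)
  expect_equal(r1$d, as.numeric(closest_distance(g, A, B)))
  expect_true(r1$p_empirical >= 1 / 101 && r1$p_empirical <= 1)
})

test_that("proximity genes are exactly the nodes on shortest paths", {
  p3 <- path_named(3)
  pg <- proximity_genes(p3, "n01", "n03")
  expect_setequal(pg$gene, c("n01", "n02", "n03"))
  expect_equal(pg$role[pg$gene == "n02"], "intermediate")

  # common genes are labelled as such
  pg2 <- proximity_genes(p3, c("n01", "n02"), c("n02", "n03"))
  expect_equal(pg2$role[pg2$gene == "n02"], "common")

  # both branches of a diamond are collected
  dia <- named_graph("a", "b", "b", "d", "a", "c", "c", "d")
  pg3 <- proximity_genes(dia, "a", "d")
  expect_setequal(pg3$gene, c("a", "b", "c", "d"))

  set.seed(53)
  for (rep in 1:15) {
    g <- er_named(8, 0.35)
    nm <- V(g)$name
    A <- sample(nm, 2); B <- sample(nm, 2)
    got <- sort(proximity_genes(g, A, B)$gene)
    expect_equal(got, oracle_proximity_genes(g, A, B))
  }
})

test_that("the pairwise matrix flags planted proximal conditions and only those", {
  flags_ok <- 0L
  for (s in 1:5) {
    g <- make_scaffold(300, m = 3, n_satellites = 0, reference_triad = FALSE,
                       seed = 200 + s)
    set.seed(300 + s)
    ref <- gene_set(sample(V(g)$name, 25), g, "ref")
    sets <- make_condition_sets(g, ref, proximal_size = 25, distal_size = 25,
                                seed = 400 + s)
    set.seed(500 + s)
    tab <- pairwise_proximity_matrix(g, list(prox = sets$proximal,
                                             dist = sets$distal),
                                     ref, run_config(n_permutations = 200))
    flags_ok <- flags_ok +
      (tab$significant[tab$condition == "prox"] &&
         !tab$significant[tab$condition == "dist"])
  }
  expect_gte(flags_ok, 4L)

  # empty condition list gives an empty table
  g <- make_scaffold(100, m = 2, n_satellites = 0, reference_triad = FALSE,
                     seed = 1)
  ref <- gene_set(V(g)$name[1:5], g, "ref")
  expect_equal(nrow(pairwise_proximity_matrix(g, list(), ref)), 0L)
})
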