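test_that("sample networks drop unexpressed genes and weight edges by expression distance", {
  g <- named_graph("a", "b", "b", "c")
  co <- toy_cohort(matrix(c(1, 3, 0), 3, 1,
                          dimnames = list(c("a", "b", "c"), "S1")),
                   c(S1 = 3))
  net <- build_sample_network(co, "S1", g)
  expect_setequal(V(net$graph)$name, c("a", "b"))
  expect_equal(E(net$graph)$weight, 2)
  expect_equal(net$n_removed, 1L)

  # all expressions equal: zero weights
  co2 <- toy_cohort(matrix(5, 3, 1, dimnames = list(c("a", "b", "c"), "S1")),
                    c(S1 = 3))
  net2 <- build_sample_network(co2, "S1", g)
  expect_true(all(E(net2$graph)$weight == 0))

  # scaffold gene absent from the matrix is treated as unexpressed
  co3 <- toy_cohort(matrix(c(1, 3), 2, 1, dimnames = list(c("a", "b"), "S1")),
                    c(S1 = 3))
  net3 <- build_sample_network(co3, "S1", g)
  expect_setequal(V(net3$graph)$name, c("a", "b"))

  # fewer than two expressed genes is an error
  co4 <- toy_cohort(matrix(c(1, 0, 0), 3, 1,
                           dimnames = list(c("a", "b", "c"), "S1")),
                    c(S1 = 3))
  expect_error(build_sample_network(co4, "S1", g), "fewer than 2")
})

test_that("sample networks are insensitive to sample order and zero-expression padding", {
  g <- er_named(20, 0.3)
  set.seed(11)
  vals <- matrix(rlnorm(40), 20, 2,
                 dimnames = list(V(g)$name, c("S1", "S2")))
  co <- toy_cohort(vals, c(S1 = 1, S2 = 2))
  co_swap <- toy_cohort(vals[, c("S2", "S1")], c(S2 = 2, S1 = 1))
  n1 <- build_sample_network(co, "S1", g)
  n2 <- build_sample_network(co_swap, "S1", g)
  expect_identical(as_edgelist(n1$graph), as_edgelist(n2$graph))
  expect_identical(E(n1$graph)$weight, E(n2$graph)$weight)

  vals_pad <- rbind(vals, zzz = c(0, 0))
  g_pad <- igraph::add_vertices(g, 1, name = "zzz")
  n3 <- build_sample_network(toy_cohort(vals_pad, c(S1 = 1, S2 = 2)), "S1", g_pad)
  expect_identical(sort(V(n3$graph)$name), sort(V(n1$graph)$name))
  expect_identical(E(n3$graph)$weight, E(n1$graph)$weight)
})

test_that("weight binning uses floor(sqrt(nodes)) equal-width bins with a closed top bin", {
  # 9 expressed nodes in a path, weights 0,1,2,3 among the first edges
  nodes <- letters[1:9]
  g <- named_graph("a", "b", "b", "c", "c", "d", "d", "e")
  g <- igraph::add_vertices(g, 4, name = nodes[6:9])
  expr <- c(a = 5, b = 5, c = 6, d = 8, e = 11, f = 1, g = 1, h = 1, i = 1)
  co <- toy_cohort(matrix(expr, 9, 1, dimnames = list(names(expr), "S1")),
                   c(S1 = 1))
  net <- build_sample_network(co, "S1", g)
  bw <- bin_weights(net)
  expect_equal(bw$n_bins, 3L)  # floor(sqrt(9))
  expect_equal(sort(E(net$graph)$weight), c(0, 1, 2, 3))
  expect_equal(sum(bw$counts), ecount(net$graph))
  expect_equal(unname(bw$counts), c(1L, 1L, 2L))  # [0,1), [1,2), [2,3]

  # all-equal weights collapse into a single occupied bin
  co2 <- toy_cohort(matrix(rep(c(2, 4), length.out = 9), 9, 1,
                           dimnames = list(nodes, "S1")), c(S1 = 1))
  g2 <- named_graph("a", "b", "c", "d", "e", "f", "g", "h")
  net2 <- build_sample_network(co2, "S1", g2)
  bw2 <- bin_weights(net2)
  expect_true(all(bw2$bin == 1L))

  # uniform weights on [0,1] with 100 nodes give 10 bins summing to the edges
  set.seed(3)
  g3 <- er_named(100, 0.08)
  v3 <- rlnorm(100); names(v3) <- V(g3)$name
  co3 <- toy_cohort(matrix(v3, 100, 1, dimnames = list(names(v3), "S1")),
                    c(S1 = 1))
  net3 <- build_sample_network(co3, "S1", g3)
  bw3 <- bin_weights(net3)
  expect_equal(bw3$n_bins, floor(sqrt(vcount(net3$graph))))
  expect_equal(sum(bw3$counts), ecount(net3$graph))
})
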