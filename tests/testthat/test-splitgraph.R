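test_that("the published stool configuration assembles as expected", {
  g <- fig4_graph()
  expect_length(g$taxon_nodes, 2L)
  expect_identical(g$module_nodes, "M00159")
  expect_equal(nrow(g$clique_edges), 1L)
  expect_equal(nrow(g$cross_edges), 2L)
  expect_equal(g$clique_edges$weight, 0.94)
})

test_that("an empty density list reduces the graph to the network", {
  net <- make_network(c("A", "B"), c("B", "C"), c(0.9, 0.8))
  g <- build_split_graph(net, NULL)
  expect_length(g$module_nodes, 0L)
  expect_equal(nrow(g$cross_edges), 0L)
  expect_setequal(g$taxon_nodes, c("A", "B", "C"))
})

test_that("density rows naming taxa outside the universe are rejected", {
  net <- make_network("A", "B", 0.9)
  dens <- make_densities("ghost", "M1", 0.8)
  expect_error(build_split_graph(net, dens, all_taxa = c("A", "B")),
               "ghost")
  # isolated taxon allowed when inside the universe
  g <- build_split_graph(net, make_densities("C", "M1", 0.8),
                         all_taxa = c("A", "B", "C"))
  expect_true("C" %in% g$taxon_nodes)
})

test_that("the independent-set property holds on randomized inputs", {
  set.seed(31)
  for (rep in 1:30) {
    g <- random_split_graph(sample(2:8, 1), sample(0:4, 1))
    validate_split_graph(g)
    adj <- splitgraphr:::split_graph_adjacency(g)
    mods <- g$module_nodes
    if (length(mods) >= 2) {
      expect_false(any(adj[mods, mods]))
    }
    expect_false(any(diag(adj)))
  }
})

test_that("a triangle of taxa with a module adjacent to all three is one clique", {
  net <- make_network(c("t1", "t1", "t2"), c("t2", "t3", "t3"),
                      c(0.9, 0.8, 0.7))
  dens <- make_densities(c("t1", "t2", "t3"), rep("M00005", 3),
                         c(0.8, 0.7, 0.9))
  g <- build_split_graph(net, dens)
  cl <- enumerate_maximal_cliques(g)
  expect_equal(nrow(cl), 1L)
  expect_identical(cl$taxa[[1]], c("t1", "t2", "t3"))
  expect_identical(cl$module[1], "M00005")
  expect_equal(cl$size[1], 4L)
  expect_true(check_cliques(cl, g))
})

test_that("a module adjacent to only one member never joins the pair clique", {
  net <- make_network("t1", "t2", 0.9)
  dens <- make_densities("t1", "M1", 0.8)
  g <- build_split_graph(net, dens)
  cl <- enumerate_maximal_cliques(g)
  expect_setequal(clique_table_keys(cl), c("t1+t2", "M1+t1"))
})

test_that("taxa-scope enumeration reports bacteria-only maximal cliques", {
  net <- make_network("t1", "t2", 0.9)
  dens <- make_densities(c("t1", "t2"), c("M1", "M1"), c(0.8, 0.7))
  g <- build_split_graph(net, dens)
  mixed <- enumerate_maximal_cliques(g)
  expect_identical(clique_table_keys(mixed), "M1+t1+t2")
  taxa_only <- enumerate_maximal_cliques(g, scope = "taxa")
  expect_identical(clique_table_keys(taxa_only), "t1+t2")
})

test_that("enumeration matches exhaustive subset enumeration and igraph", {
  set.seed(32)
  for (rep in 1:40) {
    g <- random_split_graph(sample(2:7, 1), sample(0:3, 1),
                            p_clique = runif(1, 0.2, 0.8),
                            p_cross = runif(1, 0.1, 0.6))
    got <- enumerate_maximal_cliques(g, min_size = 1L)
    adj <- splitgraphr:::split_graph_adjacency(g)
    expect_identical(clique_table_keys(got),
                     clique_key_set(brute_force_max_cliques(adj)))
    ig_cl <- igraph::max_cliques(as_igraph(g))
    expect_identical(clique_table_keys(got),
                     clique_key_set(lapply(ig_cl, names)))
  }
})

test_that("clique weights aggregate |rho| plus densities with stable ties", {
  g <- fig4_graph()
  cl <- rank_cliques(enumerate_maximal_cliques(g), g, "sum")
  expect_equal(cl$weight[1], 0.94 + 0.89 + 0.67)  # 2.50
  clm <- rank_cliques(enumerate_maximal_cliques(g), g, "mean")
  expect_equal(clm$weight[1], (0.94 + 0.89 + 0.67) / 3)

  # negative rho contributes its magnitude
  net <- make_network("a", "b", -0.66)
  g2 <- build_split_graph(net, NULL)
  cl2 <- rank_cliques(enumerate_maximal_cliques(g2), g2)
  expect_equal(cl2$weight, 0.66)
  # mean scheme on a module-free pair equals its single |rho|
  expect_equal(rank_cliques(enumerate_maximal_cliques(g2), g2,
                            "mean")$weight, 0.66)

  expect_error(rank_cliques(cl, g, scheme = "median"), "scheme")
})

test_that("identical weights break ties by size then taxa labels", {
  net <- make_network(c("a", "x", "p", "q", "p"), c("b", "y", "q", "r", "r"),
                      c(0.5, 0.5, 0.5, 0.5, 0.5))
  g <- build_split_graph(net, NULL)
  cl <- rank_cliques(enumerate_maximal_cliques(g), g)
  # triangle p-q-r (weight 1.5) first, then the equal-weight pairs a-b, x-y
  expect_identical(vapply(cl$taxa, paste, "", collapse = "+"),
                   c("p+q+r", "a+b", "x+y"))
  cl2 <- rank_cliques(enumerate_maximal_cliques(g), g)
  expect_identical(cl, cl2)
  expect_equal(nrow(rank_cliques(enumerate_maximal_cliques(g), g,
                                 top_k = 2)), 2L)
})

test_that("check_cliques rejects incomplete or non-maximal reports", {
  net <- make_network(c("a", "b"), c("b", "c"), c(0.9, 0.8))
  g <- build_split_graph(net, NULL)
  bogus <- enumerate_maximal_cliques(g)
  bogus$taxa[[1]] <- c("a", "c")  # not adjacent
  expect_error(check_cliques(bogus, g), "not complete")
  sub <- enumerate_maximal_cliques(g)
  sub$taxa[[1]] <- "a"  # extendable by b
  expect_error(check_cliques(sub[1, ], g), "not maximal")
})
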