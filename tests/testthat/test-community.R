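test_that("modularity matches hand-computed values and the adjacency form", {
  g <- build_graph(two_k3_edges())
  expect_equal(modularity_q(g, stats::setNames(rep(1, 6), g$nodes)), 0)
  expect_equal(modularity_q(g, c(A = 1, B = 1, C = 1, D = 2, E = 2, F = 2)), 5 / 14)

  tri <- build_graph(cycle_edges(c("A", "B", "C")))
  expect_equal(modularity_q(tri, c(A = 1, B = 2, C = 3)), -1 / 3)

  expect_error(modularity_q(g, c(A = 1, B = 1)), class = "triplefocus_contract_error")
  lone <- build_graph(no_edges_tbl(), seed_nodes = c("A", "B"))
  expect_error(modularity_q(lone, c(A = 1, B = 2)), class = "triplefocus_invalid_input")
})

test_that("modularity agrees with igraph on random graphs and partitions", {
  skip_if_not_installed("igraph")
  set.seed(5)
  for (rep in 1:10) {
    nodes <- sprintf("N%02d", 1:15)
    g <- build_graph(gnp_edges(nodes, 0.3), seed_nodes = nodes)
    if (g$m == 0) next
    memb <- stats::setNames(sample(1:4, 15, TRUE), nodes)
    ig <- igraph::graph_from_data_frame(graph_edges(g), directed = FALSE,
                                        vertices = g$nodes)
    expect_equal(modularity_q(g, memb),
                 igraph::modularity(ig, memb[g$nodes]), tolerance = 1e-12)
  }
})

test_that("greedy merging recovers planted cliques and matches the exhaustive optimum", {
  g <- build_graph(two_k4_edges())
  part <- greedy_communities(g)
  expect_equal(part$communities,
               list(c("A", "B", "C", "D"), c("E", "F", "G", "H")))
  best <- best_modularity(g)
  expect_equal(part$q, best$q)
  expect_equal(part$q, modularity_q(g, part$membership))

  tri <- greedy_communities(build_graph(cycle_edges(c("A", "B", "C"))))
  expect_equal(tri$communities, list(c("A", "B", "C")))
})

test_that("greedy modularity never exceeds the exhaustive optimum on small graphs", {
  set.seed(77)
  for (rep in 1:8) {
    nodes <- LETTERS[1:sample(5:8, 1)]
    g <- build_graph(gnp_edges(nodes, 0.45), seed_nodes = nodes)
    if (g$m == 0) next
    part <- greedy_communities(g)
    expect_lte(part$q, best_modularity(g)$q + 1e-12)
    # every merge strictly increased Q, starting from the all-singletons state
    expect_true(all(part$merge_log$dq > 0))
    q0 <- modularity_q(g, stats::setNames(seq_along(g$nodes), g$nodes))
    expect_gte(part$q, q0)
    expect_equal(part$q, modularity_q(g, part$membership), tolerance = 1e-12)
  }
})

test_that("community detection is invariant to input edge ordering", {
  set.seed(19)
  nodes <- sprintf("N%02d", 1:20)
  e <- gnp_edges(nodes, 0.25)
  p1 <- greedy_communities(build_graph(e, seed_nodes = nodes))
  for (rep in 1:3) {
    p2 <- greedy_communities(build_graph(e[sample(nrow(e)), ], seed_nodes = nodes))
    expect_identical(p1$communities, p2$communities)
    expect_equal(p1$q, p2$q)
  }
})

test_that("isolated nodes stay singletons and the size filter drops them", {
  e <- dplyr::bind_rows(clique_edges(c("A", "B", "C", "D")), clique_edges(c("E", "F", "G")))
  g <- build_graph(e, seed_nodes = c(LETTERS[1:7], "Z9"))
  part <- greedy_communities(g)
  expect_true(list("Z9") %in% part$communities)
  expect_message(kept <- filter_communities(part, min_size = 3), "discarded 1")
  expect_equal(length(kept$communities), 2)
  expect_identical(filter_communities(part, min_size = 1)$communities,
                   part$communities)

  sizes_demo <- new_ppi_partition(
    list(sprintf("A%02d", 1:50), sprintf("B%02d", 1:40), c("X", "Y", "Z"), "W"),
    q = 0.5)
  expect_message(kept2 <- filter_communities(sizes_demo, 10))
  expect_equal(lengths(kept2$communities), c(50L, 40L))

  expect_equal(length(greedy_communities(build_graph(no_edges_tbl()))$communities), 0)
})

test_that("greedy detection recovers planted blocks once bridges are removed", {
  cfg <- planted_config(seed = 7)
  net <- generate_planted_network(cfg)
  g <- build_graph(net$edges, seed_nodes = names(net$truth$block_of))
  part <- suppressMessages(greedy_communities(g))
  nmi <- partition_nmi(part$membership[names(net$truth$block_of)], net$truth$block_of)
  expect_gte(nmi, 0.9)
  kept <- suppressMessages(filter_communities(part, 10))
  expect_equal(length(kept$communities), cfg$n_blocks)
})

test_that("partition NMI matches igraph's and scores identity as 1", {
  a <- c(1, 1, 2, 2, 3, 3)
  expect_equal(partition_nmi(a, a), 1)
  expect_equal(partition_nmi(a, c(2, 2, 3, 3, 1, 1)), 1)
  skip_if_not_installed("igraph")
  set.seed(23)
  for (rep in 1:10) {
    x <- sample(1:4, 30, TRUE)
    y <- sample(1:3, 30, TRUE)
    expect_equal(partition_nmi(x, y),
                 igraph::compare(x, y, method = "nmi"), tolerance = 1e-12)
  }
})
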