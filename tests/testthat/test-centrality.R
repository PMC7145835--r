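test_that("degree centrality matches closed forms on star and path graphs", {
  star <- build_graph(star_edges("C0", paste0("L", 1:4)))
  cd <- degree_centrality(star)
  expect_equal(cd$degree_centrality[cd$gene == "C0"], 1)
  expect_equal(cd$degree_centrality[cd$gene != "C0"], rep(0.25, 4))

  p3 <- degree_centrality(build_graph(path_edges(c("A", "B", "C"))))
  expect_equal(p3$degree_centrality, c(0.5, 1, 0.5))

  set.seed(2)
  g <- build_graph(gnp_edges(sprintf("N%02d", 1:25), 0.3))
  expect_equal(mean(degree_centrality(g)$degree_centrality),
               2 * g$m / (g$n * (g$n - 1)))

  tiny <- build_graph(no_edges_tbl(), seed_nodes = "A")
  expect_warning(cd1 <- degree_centrality(tiny), "n < 2")
  expect_equal(cd1$degree_centrality, 0)
})

test_that("betweenness matches closed forms: path, star, cycle, disconnected", {
  p3 <- betweenness_centrality(build_graph(path_edges(c("A", "B", "C"))))
  expect_equal(p3$betweenness_centrality, c(0, 1, 0))

  star <- betweenness_centrality(build_graph(star_edges("C0", paste0("L", 1:5))))
  expect_equal(star$betweenness_centrality[star$gene == "C0"], 1)
  expect_equal(star$betweenness_centrality[star$gene != "C0"], rep(0, 5))

  cyc <- betweenness_centrality(build_graph(cycle_edges(paste0("V", 1:5))))
  expect_equal(cyc$betweenness_centrality, rep(1 / 6, 5))

  two_tri <- betweenness_centrality(build_graph(dplyr::bind_rows(
    clique_edges(c("A", "B", "C")), clique_edges(c("D", "E", "F")))))
  expect_equal(two_tri$betweenness_centrality, rep(0, 6))
})

test_that("betweenness agrees exactly with the path-enumeration oracle on random graphs", {
  set.seed(101)
  for (rep in 1:60) {
    n <- sample(4:12, 1)
    p <- sample(c(0.2, 0.5, 0.8), 1)
    g <- build_graph(gnp_edges(sprintf("N%02d", seq_len(n)), p),
                     seed_nodes = sprintf("N%02d", seq_len(n)))
    fast <- betweenness_centrality(g)
    slow <- betweenness_oracle(g)
    expect_equal(fast, slow, tolerance = 1e-12)
    expect_true(all(fast$betweenness_centrality >= 0 &
                    fast$betweenness_centrality <= 1))
  }
  expect_error(betweenness_oracle(build_graph(clique_edges(sprintf("N%02d", 1:16)))),
               class = "triplefocus_invalid_input")
})

test_that("betweenness agrees with igraph on larger graphs", {
  skip_if_not_installed("igraph")
  set.seed(17)
  for (rep in 1:5) {
    g <- build_graph(gnp_edges(sprintf("N%02d", 1:40), 0.12),
                     seed_nodes = sprintf("N%02d", 1:40))
    e <- graph_edges(g)
    ig <- igraph::graph_from_data_frame(e, directed = FALSE,
                                        vertices = g$nodes)
    ref <- igraph::betweenness(ig, directed = FALSE) * 2 / ((g$n - 1) * (g$n - 2))
    mine <- betweenness_centrality(g)
    expect_equal(mine$betweenness_centrality,
                 unname(ref[mine$gene]), tolerance = 1e-10)
  }
})

test_that("betweenness is invariant under node relabeling", {
  set.seed(31)
  base <- sprintf("N%02d", 1:10)
  e <- gnp_edges(base, 0.4)
  g <- build_graph(e, seed_nodes = base)
  b1 <- betweenness_centrality(g)
  for (rep in 1:5) {
    perm <- stats::setNames(sample(sprintf("M%02d", 1:10)), base)
    g2 <- build_graph(edge_tbl(perm[e$node_a], perm[e$node_b]),
                      seed_nodes = unname(perm))
    b2 <- betweenness_centrality(g2)
    expect_equal(stats::setNames(b2$betweenness_centrality, b2$gene)[perm[b1$gene]],
                 stats::setNames(b1$betweenness_centrality, perm[b1$gene]))
  }
})

test_that("closing a path's endpoints cannot raise the middle node's betweenness", {
  open_path <- betweenness_centrality(build_graph(path_edges(c("A", "B", "C"))))
  closed <- betweenness_centrality(build_graph(cycle_edges(c("A", "B", "C"))))
  expect_lte(closed$betweenness_centrality[closed$gene == "B"],
             open_path$betweenness_centrality[open_path$gene == "B"])
})

test_that("node ranking is stable, deterministic and tie-broken lexicographically", {
  ct <- centrality_table(build_graph(path_edges(c("A", "B", "C"))))
  expect_equal(rank_nodes(ct, "betweenness_centrality", 1)$gene, "B")
  expect_equal(nrow(rank_nodes(ct, top_k = 0)), 0)

  flat <- tibble::tibble(gene = c("Z", "M", "A"), betweenness_centrality = 0.5)
  expect_equal(rank_nodes(flat, "betweenness_centrality")$gene, c("A", "M", "Z"))
  expect_error(rank_nodes(flat, "degree_centrality"),
               class = "triplefocus_invalid_input")
})
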