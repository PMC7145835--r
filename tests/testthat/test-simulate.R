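k4_pair_config <- function(seed = 1) {
  planted_config(n_blocks = 2, block_size = 4, p_in = 1, p_out = 0,
                 n_bridges = 1, bridge_degree = 2,
                 set_a_frac = 0.5, set_b_frac = 0.5,
                 drug_set_size = 1, drug_bridge_count = 1, seed = seed)
}

test_that("clique-block config yields the exact planted structure", {
  net <- generate_planted_network(k4_pair_config())
  # two K4 blocks (6 edges each) plus one bridge with 2 edges into each block
  expect_equal(nrow(net$edges), 2 * 6 + 4)
  bridge <- net$truth$bridges
  expect_length(bridge, 1)
  g <- build_graph(net$edges)
  expect_equal(length(g$adj[[bridge]]), 4)
  blocks_hit <- unique(net$truth$block_of[g$adj[[bridge]]])
  expect_setequal(blocks_hit, 1:2)
  expect_true(all(net$edges$score >= 401 & net$edges$score <= 1000))
})

test_that("generation is deterministic and produces a simple undirected graph", {
  cfg <- planted_config(seed = 13)
  n1 <- generate_planted_network(cfg)
  n2 <- generate_planted_network(cfg)
  expect_identical(n1$edges, n2$edges)
  expect_identical(n1$truth$block_of, n2$truth$block_of)

  e <- n1$edges
  expect_true(all(e$node_a != e$node_b))
  expect_equal(anyDuplicated(paste(e$node_a, e$node_b)), 0)
  expect_true(all(e$node_a < e$node_b))

  # byte-identical serialized outputs under the same seed
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_edge_list(n1$edges, f1)
  write_edge_list(generate_planted_network(cfg)$edges, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("invalid planted configurations are rejected", {
  expect_error(planted_config(p_in = 0.2, p_out = 0.3),
               class = "triplefocus_invalid_config")
  expect_error(planted_config(p_in = 0.02, block_size = 25),
               "within-block degree", class = "triplefocus_invalid_config")
  expect_error(planted_config(n_bridges = 5, drug_set_size = 3),
               class = "triplefocus_invalid_config")
  expect_error(planted_config(set_a_frac = 0.7, set_b_frac = 0.6),
               class = "triplefocus_invalid_config")
  expect_error(planted_config(drug_bridge_count = 9, n_bridges = 4,
                              drug_set_size = 12),
               class = "triplefocus_invalid_config")
})

test_that("gene sets overlap exactly on the planted bridges", {
  cfg <- planted_config(seed = 7)
  net <- generate_planted_network(cfg)
  sets <- generate_gene_sets(net$truth)
  expect_setequal(node_overlap(sets$set_a, sets$set_b), net$truth$bridges)
  expect_gte(length(node_overlap(sets$set_a, sets$set_b)), cfg$n_bridges)
  triple <- node_overlap(sets$set_a, sets$set_b, sets$drug_set)
  expect_gte(length(triple), cfg$drug_bridge_count)
  expect_equal(length(sets$drug_set), cfg$drug_set_size)

  sets2 <- generate_gene_sets(net$truth)
  expect_identical(lapply(sets, `[[`, "members"), lapply(sets2, `[[`, "members"))
})

test_that("pathways mirror blocks with a controlled noise fraction", {
  cfg <- planted_config(seed = 2)
  truth <- generate_planted_network(cfg)$truth
  clean <- generate_pathways(truth, noise_frac = 0)
  for (b in seq_len(cfg$n_blocks)) {
    expect_setequal(clean$genes[[b]], names(truth$block_of)[truth$block_of == b])
  }
  noisy <- generate_pathways(truth, noise_frac = 0.1)
  for (b in seq_len(cfg$n_blocks)) {
    expect_length(noisy$genes[[b]], cfg$block_size)
    own <- intersect(noisy$genes[[b]], names(truth$block_of)[truth$block_of == b])
    expect_gte(length(own), cfg$block_size - floor(0.1 * cfg$block_size))
  }
  expect_error(generate_pathways(truth, noise_frac = 0.5),
               class = "triplefocus_invalid_config")
})

test_that("planted truth serializes with block and bridge annotation", {
  net <- generate_planted_network(k4_pair_config())
  f <- withr::local_tempfile(fileext = ".tsv")
  write_planted_truth(net$truth, f)
  tbl <- utils::read.delim(f)
  expect_equal(nrow(tbl), 9)
  expect_equal(sum(tbl$is_bridge), 1)
  expect_setequal(tbl$block[!tbl$is_bridge], 1:2)
})

test_that("bridges dominate the betweenness ranking of the full planted graph", {
  # recorded 77/100 over seeds 1..100 when the threshold was frozen; the
  # occasional miss is an inter-block edge endpoint out-ranking one bridge
  hits <- 0
  for (s in 1:100) {
    net <- generate_planted_network(planted_config(seed = s))
    g <- build_graph(net$edges)
    top4 <- rank_nodes(centrality_table(g), "betweenness_centrality", 4)$gene
    if (setequal(top4, net$truth$bridges)) hits <- hits + 1
  }
  expect_gte(hits, 75)
})
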