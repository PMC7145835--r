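# In-code fixtures and independent oracles shared across the suite.

no_edges_tbl <- function() {
  tibble::tibble(node_a = character(), node_b = character(), score = integer())
}

edge_tbl <- function(a, b, score = 1000L) {
  tibble::tibble(node_a = a, node_b = b, score = as.integer(score))
}

path_edges <- function(nodes) {
  edge_tbl(nodes[-length(nodes)], nodes[-1])
}

cycle_edges <- function(nodes) {
  edge_tbl(nodes, c(nodes[-1], nodes[1]))
}

star_edges <- function(center, leaves) {
  edge_tbl(rep(center, length(leaves)), leaves)
}

clique_edges <- function(nodes) {
  pr <- utils::combn(nodes, 2)
  edge_tbl(pr[1, ], pr[2, ])
}

# G(n, p) over the given symbols, deterministic under the ambient seed
gnp_edges <- function(nodes, p) {
  pr <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(pr)) < p
  edge_tbl(pr[1, keep], pr[2, keep])
}

# two K3 cliques A,B,C and D,E,F joined by edge C-D
two_k3_edges <- function() {
  dplyr::bind_rows(clique_edges(c("A", "B", "C")),
                   clique_edges(c("D", "E", "F")),
                   edge_tbl("C", "D"))
}

# two K4 cliques joined by one edge
two_k4_edges <- function() {
  dplyr::bind_rows(clique_edges(c("A", "B", "C", "D")),
                   clique_edges(c("E", "F", "G", "H")),
                   edge_tbl("D", "E"))
}

# all set partitions of a character vector (Bell-number enumeration)
all_set_partitions <- function(items) {
  if (length(items) == 0) return(list(list()))
  first <- items[1]
  rest <- all_set_partitions(items[-1])
  out <- list()
  for (part in rest) {
    for (i in seq_along(part)) {
      p2 <- part
      p2[[i]] <- c(first, p2[[i]])
      out[[length(out) + 1]] <- p2
    }
    out[[length(out) + 1]] <- c(part, list(first))
  }
  out
}

partition_to_membership <- function(part) {
  stats::setNames(rep(seq_along(part), lengths(part)),
                  unlist(part, use.names = FALSE))
}

# exhaustive-search modularity optimum over all partitions (small graphs only)
best_modularity <- function(g) {
  stopifnot(g$n <= 8)
  parts <- all_set_partitions(g$nodes)
  qs <- vapply(parts, function(p) modularity_q(g, partition_to_membership(p)), 0)
  list(q = max(qs), partition = parts[[which.max(qs)]])
}

# upper hypergeometric tail from integer binomial coefficients (independent
# of phyper); exact for N <= 40 where choose() stays below 2^53
hyper_tail_bruteforce <- function(k, K, s, N) {
  i <- k:min(K, s)
  sum(choose(K, i) * choose(N - K, s - i)) / choose(N, s)
}

# BH step-up recursion written directly from its definition
bh_stepup_reference <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- ps * m / seq_len(m)
  for (i in rev(seq_len(m - 1))) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

expect_same_tbl <- function(a, b) {
  expect_equal(as.data.frame(a), as.data.frame(b))
}
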