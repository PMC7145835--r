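#' Build a simple undirected PPI graph from interaction records
#'
#' With `seed_nodes` supplied, returns the induced subgraph on the seed
#' gene list: only edges with both endpoints in the seed set are kept, and
#' every seed symbol becomes a node even if it has no surviving interaction
#' (isolated nodes are retained, so the node count equals the gene-list
#' size). Without seeds, the nodes are exactly the edge endpoints.
#'
#' @param edges Tibble of interaction records (`node_a`, `node_b`, optional
#'   `score`) as returned by [read_edge_list()].
#' @param seed_nodes Optional [gene_set] or character vector restricting the
#'   graph to an induced subgraph.
#' @return A `ppi_graph`: node set plus symmetric adjacency, no self-loops,
#'   no parallel edges.
#' @export
#' @examples
#' edges <- tibble::tibble(node_a = c("A", "B"), node_b = c("B", "C"))
#' build_graph(edges, seed_nodes = c("A", "B", "X"))
build_graph <- function(edges, seed_nodes = NULL) {
  edges <- as_edge_tbl(edges)
  if (!is.null(seed_nodes)) {
    seeds <- as_members(seed_nodes, "seed_nodes")
    edges <- dplyr::filter(edges, .data$node_a %in% seeds, .data$node_b %in% seeds)
    nodes <- seeds
  } else {
    nodes <- sort(unique(c(edges$node_a, edges$node_b)))
  }
  new_ppi_graph(nodes, edges$node_a, edges$node_b)
}

new_ppi_graph <- function(nodes, from, to) {
  nodes <- sort(unique(nodes))
  adj <- vector("list", length(nodes))
  names(adj) <- nodes
  if (length(from)) {
    nb <- split(c(to, from), c(from, to))
    nb <- lapply(nb, function(v) sort(unique(v)))
    adj[names(nb)] <- nb
  }
  empty <- vapply(adj, is.null, logical(1))
  adj[empty] <- list(character(0))
  structure(
    list(
      nodes = nodes,
      adj = adj,
      n = length(nodes),
      m = as.integer(sum(lengths(adj)) / 2)
    ),
    class = "ppi_graph"
  )
}

#' @export
print.ppi_graph <- function(x, ...) {
  cat(sprintf("<ppi_graph> %d nodes, %d edges\n", x$n, x$m))
  invisible(x)
}

#' Edge table of a graph
#'
#' @param g A `ppi_graph`.
#' @return Tibble with columns `node_a`, `node_b` (node_a < node_b), sorted.
#' @export
graph_edges <- function(g) {
  stopifnot(inherits(g, "ppi_graph"))
  from <- rep(names(g$adj), lengths(g$adj))
  to <- unlist(g$adj, use.names = FALSE)
  keep <- from < to
  tibble::tibble(node_a = from[keep], node_b = to[keep]) |>
    dplyr::arrange(.data$node_a, .data$node_b)
}

#' Union of two PPI networks
#'
#' The combined network: node set is the union of the node sets, edge set
#' the union of the edge sets. Commutative and idempotent.
#'
#' @param g1,g2 `ppi_graph` objects.
#' @return A `ppi_graph`.
#' @export
union_graphs <- function(g1, g2) {
  stopifnot(inherits(g1, "ppi_graph"), inherits(g2, "ppi_graph"))
  e <- dplyr::distinct(dplyr::bind_rows(graph_edges(g1), graph_edges(g2)))
  new_ppi_graph(c(g1$nodes, g2$nodes), e$node_a, e$node_b)
}

#' Shared symbols across networks or gene sets
#'
#' Intersection of the symbol sets of any mix of graphs, gene sets and
#' character vectors, in deterministic lexicographic order.
#'
#' @param ... Two or more `ppi_graph`, [gene_set] or character objects.
#' @return Sorted character vector of shared symbols.
#' @export
#' @examples
#' node_overlap(c("A", "B", "C"), c("B", "C", "D"))
node_overlap <- function(...) {
  sets <- lapply(list(...), as_members)
  if (length(sets) < 2) {
    abort("node_overlap() needs at least two collections.",
          class = "triplefocus_invalid_input")
  }
  sort(Reduce(intersect, sets))
}

#' Connected components of a graph
#'
#' @param g A `ppi_graph`.
#' @return Named integer vector: component id (1-based, by order of
#'   discovery over sorted nodes) for every node.
#' @export
graph_components <- function(g) {
  stopifnot(inherits(g, "ppi_graph"))
  comp <- stats::setNames(rep(NA_integer_, g$n), g$nodes)
  cid <- 0L
  for (v in g$nodes) {
    if (!is.na(comp[[v]])) next
    cid <- cid + 1L
    queue <- v
    comp[[v]] <- cid
    while (length(queue)) {
      u <- queue[[1]]
      queue <- queue[-1]
      nb <- g$adj[[u]]
      new <- nb[is.na(comp[nb])]
      comp[new] <- cid
      queue <- c(queue, new)
    }
  }
  comp
}

#' Summarize a network as one characteristics row
#'
#' Produces the standard network characteristics row: node count, edge
#' count, and the mean over all nodes of normalized degree centrality and
#' normalized betweenness centrality. Isolated nodes are included in both
#' means. For n < 2 the centrality means are reported as 0.
#'
#' @param g A `ppi_graph`.
#' @param name Network label for the row.
#' @param truncated Also include the means truncated toward zero at 3
#'   significant figures (the table reporting convention). Default TRUE.
#' @return One-row tibble: `network`, `nodes`, `edges`,
#'   `avg_degree_centrality`, `avg_betweenness_centrality` and, if
#'   requested, their `*_3sf` truncations.
#' @export
summarize_network <- function(g, name, truncated = TRUE) {
  stopifnot(inherits(g, "ppi_graph"))
  if (g$n < 2) {
    mean_cd <- 0
    mean_cb <- 0
  } else {
    ct <- centrality_table(g)
    mean_cd <- mean(ct$degree_centrality)
    mean_cb <- mean(ct$betweenness_centrality)
  }
  out <- tibble::tibble(
    network = name,
    nodes = g$n,
    edges = g$m,
    avg_degree_centrality = mean_cd,
    avg_betweenness_centrality = mean_cb
  )
  if (truncated) {
    out$avg_degree_centrality_3sf <- truncate_signif(mean_cd, 3)
    out$avg_betweenness_centrality_3sf <- truncate_signif(mean_cb, 3)
  }
  out
}
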