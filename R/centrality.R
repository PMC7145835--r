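#' Normalized degree centrality
#'
#' C_D(v) = deg(v) / (n - 1): the degree divided by the maximum possible
#' degree in a simple graph of n nodes. Isolated nodes score 0. For n < 2
#' all values are 0 and a warning is emitted.
#'
#' @param g A `ppi_graph`.
#' @return Tibble with columns `gene`, `degree_centrality`, one row per
#'   node in lexicographic order.
#' @export
degree_centrality <- function(g) {
  stopifnot(inherits(g, "ppi_graph"))
  if (g$n < 2) {
    if (g$n > 0) warn("degree_centrality: n < 2, all values set to 0.")
    return(tibble::tibble(gene = g$nodes,
                          degree_centrality = rep(0, g$n)))
  }
  tibble::tibble(
    gene = g$nodes,
    degree_centrality = unname(lengths(g$adj)[g$nodes]) / (g$n - 1)
  )
}

# integer-indexed adjacency for the traversal kernels
adj_index <- function(g) {
  idx <- seq_along(g$nodes)
  names(idx) <- g$nodes
  lapply(g$adj, function(nb) unname(idx[nb]))
}

#' Normalized shortest-path betweenness centrality
#'
#' Brandes' accumulation algorithm on the unweighted, undirected graph.
#' The raw score of v sums, over unordered node pairs \{s, t\} with s, t
#' distinct from v and at least one geodesic, the fraction of s--t
#' geodesics passing through v; unreachable pairs contribute nothing and
#' there is no per-component rescaling. Normalization divides by
#' (n - 1)(n - 2) / 2, the number of pairs excluding v, so values lie in
#' \[0, 1\]; for n < 3 all values are 0.
#'
#' @param g A `ppi_graph`.
#' @return Tibble with columns `gene`, `betweenness_centrality`, one row
#'   per node in lexicographic order.
#' @export
betweenness_centrality <- function(g) {
  stopifnot(inherits(g, "ppi_graph"))
  raw <- brandes_raw(g)
  norm <- if (g$n >= 3) 2 / ((g$n - 1) * (g$n - 2)) else 0
  tibble::tibble(gene = g$nodes, betweenness_centrality = raw * norm)
}

# raw betweenness over unordered pairs, endpoints excluded
brandes_raw <- function(g) {
  n <- g$n
  cb <- numeric(n)
  if (n < 3) return(cb)
  adj <- adj_index(g)
  for (s in seq_len(n)) {
    stack <- integer(n)
    sp <- 0L
    preds <- vector("list", n)
    sigma <- numeric(n)
    sigma[s] <- 1
    dist <- rep(-1L, n)
    dist[s] <- 0L
    queue <- integer(n)
    queue[1] <- s
    qh <- 1L
    qt <- 1L
    while (qh <= qt) {
      v <- queue[qh]
      qh <- qh + 1L
      sp <- sp + 1L
      stack[sp] <- v
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          qt <- qt + 1L
          queue[qt] <- w
          dist[w] <- dist[v] + 1L
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (i in rev(seq_len(sp))) {
      w <- stack[i]
      coef <- (1 + delta[w]) / sigma[w]
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] * coef
      }
      if (w != s) cb[w] <- cb[w] + delta[w]
    }
  }
  cb / 2
}

#' Per-node centrality table
#'
#' Joins [degree_centrality()] and [betweenness_centrality()] into the
#' per-node table written alongside every network (the ranked-node table
#' analog).
#'
#' @param g A `ppi_graph`.
#' @return Tibble with columns `gene`, `degree_centrality`,
#'   `betweenness_centrality`.
#' @export
centrality_table <- function(g) {
  dplyr::inner_join(degree_centrality(g), betweenness_centrality(g), by = "gene")
}

#' Brute-force betweenness oracle
#'
#' Independent reference implementation for testing: all-pairs distances by
#' Floyd--Warshall, then explicit recursive enumeration of every geodesic
#' of every pair, counting interior occurrences per node. Same
#' normalization contract as [betweenness_centrality()]. Refuses graphs
#' with more than `max_n` nodes (path enumeration is exponential).
#'
#' @param g A `ppi_graph` with at most `max_n` nodes.
#' @param max_n Size cap (default 15).
#' @return Tibble with columns `gene`, `betweenness_centrality`.
#' @export
betweenness_oracle <- function(g, max_n = 15) {
  stopifnot(inherits(g, "ppi_graph"))
  if (g$n > max_n) {
    abort(sprintf("betweenness_oracle: graph has %d nodes, cap is %d.", g$n, max_n),
          class = "triplefocus_invalid_input")
  }
  n <- g$n
  raw <- numeric(n)
  if (n >= 3) {
    adj <- adj_index(g)
    d <- matrix(Inf, n, n)
    diag(d) <- 0
    for (v in seq_len(n)) d[v, adj[[v]]] <- 1
    for (k in seq_len(n)) {
      for (i in seq_len(n)) {
        nd <- d[i, k] + d[k, ]
        upd <- nd < d[i, ]
        d[i, upd] <- nd[upd]
      }
    }
    enumerate_paths <- function(s, t) {
      if (s == t) return(list(s))
      out <- list()
      for (w in adj[[s]]) {
        if (d[w, t] == d[s, t] - 1) {
          for (p in enumerate_paths(w, t)) out[[length(out) + 1]] <- c(s, p)
        }
      }
      out
    }
    for (s in seq_len(n - 1)) {
      for (t in seq(s + 1, n)) {
        if (!is.finite(d[s, t])) next
        paths <- enumerate_paths(s, t)
        if (length(paths) == 0) next
        interior <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
        if (length(interior)) {
          counts <- tabulate(interior, nbins = n)
          raw <- raw + counts / length(paths)
        }
      }
    }
  }
  norm <- if (n >= 3) 2 / ((n - 1) * (n - 2)) else 0
  tibble::tibble(gene = g$nodes, betweenness_centrality = raw * norm)
}

#' Rank nodes by a centrality measure
#'
#' Descending by the chosen value with lexicographic tie-break on the gene
#' symbol, so rankings are stable and deterministic.
#'
#' @param table A centrality tibble with a `gene` column.
#' @param by Column to sort by: `"betweenness_centrality"` (default) or
#'   `"degree_centrality"`.
#' @param top_k Number of rows to keep (default all; `top_k <= 0` gives an
#'   empty table).
#' @return Tibble of the top rows in rank order.
#' @export
rank_nodes <- function(table, by = "betweenness_centrality", top_k = Inf) {
  stopifnot(is.data.frame(table), "gene" %in% names(table))
  if (!by %in% names(table)) {
    abort(sprintf("rank_nodes: no column '%s' in table.", by),
          class = "triplefocus_invalid_input")
  }
  if (top_k <= 0) return(table[0, , drop = FALSE])
  out <- dplyr::arrange(table, dplyr::desc(.data[[by]]), .data$gene)
  head(out, top_k)
}
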