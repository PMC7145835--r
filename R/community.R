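#' Modularity Q of a partition
#'
#' Newman--Girvan modularity: Q = sum over communities c of
#' L_c / m - (D_c / 2m)^2, with L_c the number of edges inside c, D_c the
#' total degree of c's members and m the edge count. Equivalent to the
#' (1/2m) sum_ij (A_ij - k_i k_j / 2m) delta(c_i, c_j) form.
#'
#' @param g A `ppi_graph` with at least one edge.
#' @param membership Named vector (names = gene symbols) assigning every
#'   node of `g` to a community; any label type.
#' @return Modularity Q, a value in \[-0.5, 1).
#' @export
#' @examples
#' g <- build_graph(tibble::tibble(node_a = c("A", "B"), node_b = c("B", "C")))
#' modularity_q(g, c(A = 1, B = 1, C = 1))  # single community: 0
modularity_q <- function(g, membership) {
  stopifnot(inherits(g, "ppi_graph"))
  if (g$m == 0) {
    abort("modularity_q: undefined for a graph with no edges.",
          class = "triplefocus_invalid_input")
  }
  if (is.null(names(membership)) || !setequal(names(membership), g$nodes)) {
    abort("modularity_q: `membership` must cover exactly the graph's nodes.",
          class = "triplefocus_contract_error")
  }
  m <- g$m
  memb <- membership[g$nodes]
  deg <- lengths(g$adj)[g$nodes]
  d_c <- tapply(deg, memb, sum)
  e <- graph_edges(g)
  within <- memb[e$node_a] == memb[e$node_b]
  l_c <- tapply(within, memb[e$node_a], sum)
  l_full <- stats::setNames(rep(0, length(d_c)), names(d_c))
  l_full[names(l_c)] <- l_c
  sum(l_full / m - (d_c / (2 * m))^2)
}

new_ppi_partition <- function(communities, q, merge_log = NULL) {
  # deterministic ids: decreasing size, ties by lexicographically first member
  if (length(communities)) {
    communities <- lapply(communities, sort)
    ord <- order(-lengths(communities),
                 vapply(communities, `[`, "", 1))
    communities <- communities[ord]
  }
  membership <- stats::setNames(
    rep(seq_along(communities), lengths(communities)),
    unlist(communities, use.names = FALSE)
  )
  structure(
    list(communities = communities, membership = membership,
         q = q, merge_log = merge_log),
    class = "ppi_partition"
  )
}

#' @export
print.ppi_partition <- function(x, ...) {
  cat(sprintf("<ppi_partition> %d communities over %d nodes, Q = %.4f\n",
              length(x$communities), length(x$membership), x$q))
  if (length(x$communities)) {
    cat("  sizes:", paste(lengths(x$communities), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.ppi_partition <- function(x, ...) {
  tibble::tibble(gene = names(x$membership),
                 community = unname(x$membership)) |>
    dplyr::arrange(.data$community, .data$gene)
}

#' @export
glance.ppi_partition <- function(x, ...) {
  sizes <- lengths(x$communities)
  tibble::tibble(
    q = x$q,
    n_communities = length(x$communities),
    n_nodes = length(x$membership),
    largest = if (length(sizes)) max(sizes) else 0L,
    smallest = if (length(sizes)) min(sizes) else 0L
  )
}

#' Greedy modularity maximization (CNM) community detection
#'
#' Agglomerative scheme: every node starts in its own community and the
#' pair of communities whose merge most increases modularity is joined,
#' repeatedly, until no merge increases Q. Among pairs with equal gain the
#' pair whose (smaller, larger) lexicographic community labels sort first
#' is merged, where a community is labelled by its lexicographically
#' smallest member; this makes the result invariant to input ordering.
#' Isolated nodes remain singleton communities.
#'
#' @param g A `ppi_graph`; needs at least one edge unless empty.
#' @return A `ppi_partition`: communities in decreasing size order with
#'   deterministic ids, the achieved modularity `q`, and a `merge_log`
#'   tibble (step, communities merged, dQ, Q after).
#' @export
greedy_communities <- function(g) {
  stopifnot(inherits(g, "ppi_graph"))
  if (g$n == 0) {
    return(new_ppi_partition(list(), q = NA_real_,
                             merge_log = empty_merge_log()))
  }
  if (g$m == 0) {
    abort("greedy_communities: graph has no edges; modularity is undefined.",
          class = "triplefocus_invalid_input")
  }
  m <- g$m
  members <- as.list(g$nodes)
  names(members) <- g$nodes
  deg_sum <- stats::setNames(as.numeric(lengths(g$adj)[g$nodes]), g$nodes)
  l_within <- stats::setNames(numeric(g$n), g$nodes)
  e <- graph_edges(g)
  # conn[[u]][v]: number of edges between communities u and v (both directions kept)
  conn <- new.env(parent = emptyenv())
  for (v in g$nodes) assign(v, numeric(0), envir = conn)
  for (i in seq_len(nrow(e))) {
    a <- e$node_a[i]; b <- e$node_b[i]
    ca <- get(a, envir = conn); ca[b] <- 1; assign(a, ca, envir = conn)
    cb <- get(b, envir = conn); cb[a] <- 1; assign(b, cb, envir = conn)
  }
  q <- -sum((deg_sum / (2 * m))^2)
  log_step <- integer(0); log_into <- character(0)
  log_from <- character(0); log_dq <- numeric(0); log_q <- numeric(0)
  step <- 0L
  repeat {
    labels <- sort(names(members))
    best_dq <- 0
    best_u <- NA_character_; best_v <- NA_character_
    for (u in labels) {
      cu <- get(u, envir = conn)
      if (!length(cu)) next
      vs <- names(cu)
      vs <- vs[vs > u]
      if (!length(vs)) next
      dq <- cu[vs] / m - 2 * (deg_sum[u] / (2 * m)) * (deg_sum[vs] / (2 * m))
      j <- which(dq > best_dq + 1e-12)
      if (length(j)) {
        # labels scanned in sorted order, vs sorted: first hit wins ties
        jbest <- j[which.max(dq[j])]
        cand <- unname(dq[jbest])
        if (cand > best_dq + 1e-12) {
          best_dq <- cand; best_u <- u; best_v <- vs[jbest]
        }
      }
    }
    if (is.na(best_u)) break
    u <- best_u; v <- best_v
    cu <- get(u, envir = conn); cv <- get(v, envir = conn)
    l_within[u] <- l_within[u] + l_within[v] + cu[[v]]
    deg_sum[u] <- deg_sum[u] + deg_sum[v]
    members[[u]] <- c(members[[u]], members[[v]])
    members[[v]] <- NULL
    cu <- cu[names(cu) != v]
    cv <- cv[names(cv) != u]
    for (w in names(cv)) {
      cw <- get(w, envir = conn)
      cw <- cw[names(cw) != v]
      cw[u] <- (if (u %in% names(cw)) cw[[u]] else 0) + cv[[w]]
      assign(w, cw, envir = conn)
      cu[w] <- (if (w %in% names(cu)) cu[[w]] else 0) + cv[[w]]
    }
    assign(u, cu, envir = conn)
    rm(list = v, envir = conn)
    l_within[v] <- 0
    deg_sum <- deg_sum[names(deg_sum) != v]
    q <- q + best_dq
    step <- step + 1L
    log_step <- c(log_step, step); log_into <- c(log_into, u)
    log_from <- c(log_from, v); log_dq <- c(log_dq, best_dq); log_q <- c(log_q, q)
  }
  merge_log <- tibble::tibble(step = log_step, into = log_into,
                              from = log_from, dq = log_dq, q = log_q)
  part <- new_ppi_partition(unname(members), q = q, merge_log = merge_log)
  part
}

empty_merge_log <- function() {
  tibble::tibble(step = integer(), into = character(), from = character(),
                 dq = numeric(), q = numeric())
}

#' Drop communities below a minimum size
#'
#' Keeps communities with at least `min_size` members (the
#' "biologically meaningful" filter applied before enrichment); the number
#' discarded is reported as a message. Kept communities retain their
#' relative order and are re-numbered 1..k; the stored Q still refers to
#' the full partition it came from.
#'
#' @param partition A `ppi_partition`.
#' @param min_size Minimum community size (default 10).
#' @return A `ppi_partition` containing the kept communities.
#' @export
filter_communities <- function(partition, min_size = 10) {
  stopifnot(inherits(partition, "ppi_partition"), min_size >= 1)
  keep <- lengths(partition$communities) >= min_size
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    inform(sprintf("filter_communities: discarded %d communit%s below size %d",
                   n_drop, if (n_drop == 1) "y" else "ies", min_size))
  }
  out <- new_ppi_partition(partition$communities[keep], q = partition$q,
                           merge_log = partition$merge_log)
  out
}
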