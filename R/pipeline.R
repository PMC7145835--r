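#' Run the triple-focusing network analysis
#'
#' End-to-end pipeline over two disease gene sets, an interaction edge
#' list and (optionally) a drug-perturbation gene set:
#' \enumerate{
#'   \item build disease networks A and B as induced subgraphs on their
#'     gene lists (isolated seeds retained);
#'   \item join them into the combined network (node and edge union);
#'   \item compute per-node normalized degree and betweenness centrality
#'     on the combined network and extract the top-k tables;
#'   \item detect communities by greedy modularity maximization, drop
#'     communities below `min_community_size`, and (when pathways are
#'     supplied) test the kept communities for pathway
#'     over-representation with joint BH adjustment;
#'   \item tabulate the A/B shared genes with their combined-network
#'     centralities;
#'   \item build the drug network (induced subgraph on the drug set),
#'     overlap it with the combined network, and rank the shared symbols
#'     by combined-network betweenness — the candidate-target table.
#' }
#' Without a drug set the pipeline runs in validation mode (steps 1--5)
#' and the ranked target table is empty. An empty triple overlap is a
#' warning, not a failure.
#'
#' @param gene_set_a,gene_set_b Disease [gene_set]s (or character vectors).
#' @param edges Interaction tibble from [read_edge_list()] (already
#'   confidence-filtered and deduplicated).
#' @param drug_set Optional drug-perturbation [gene_set].
#' @param pathways Optional `pathway_collection` for community enrichment.
#' @param min_community_size Community size cutoff before enrichment
#'   (default 10).
#' @param top_k Rows kept in the top-node tables (default 10).
#' @param background Enrichment universe: `"network"` (default; the
#'   combined network's node set) or `"pathways"` (union of all pathway
#'   genes and network nodes).
#' @return A `triple_focus_report`; see [tidy.triple_focus_report()] and
#'   [glance.triple_focus_report()].
#' @export
run_triple_focus <- function(gene_set_a, gene_set_b, edges,
                             drug_set = NULL, pathways = NULL,
                             min_community_size = 10, top_k = 10,
                             background = c("network", "pathways")) {
  background <- match.arg(background)
  a <- if (inherits(gene_set_a, "gene_set")) gene_set_a else gene_set("set_a", gene_set_a)
  b <- if (inherits(gene_set_b, "gene_set")) gene_set_b else gene_set("set_b", gene_set_b)
  edges <- as_edge_tbl(edges)

  g_a <- build_graph(edges, seed_nodes = a)
  g_b <- build_graph(edges, seed_nodes = b)
  combined <- union_graphs(g_a, g_b)
  stopifnot(combined$n == length(union(g_a$nodes, g_b$nodes)))
  inform(sprintf("triple_focus: %s %d/%d, %s %d/%d, combined %d/%d (nodes/edges)",
                 a$name, g_a$n, g_a$m, b$name, g_b$n, g_b$m, combined$n, combined$m))

  ct <- centrality_table(combined)
  top_degree <- rank_nodes(ct, "degree_centrality", top_k)
  top_betweenness <- rank_nodes(ct, "betweenness_centrality", top_k)

  partition <- greedy_communities(combined)
  kept <- filter_communities(partition, min_community_size)
  enrichment <- NULL
  if (!is.null(pathways) && length(kept$communities) > 0) {
    bg <- if (background == "network") {
      combined$nodes
    } else {
      sort(union(combined$nodes, unlist(pathways$genes, use.names = FALSE)))
    }
    enrichment <- enrich_communities(kept, pathways, bg)
  }

  shared_ab <- node_overlap(a, b)
  stopifnot(setequal(shared_ab, intersect(a$members, b$members)))
  pairwise_overlap <- rank_overlap_by_betweenness(
    intersect(shared_ab, combined$nodes), ct)

  g_drug <- NULL
  triple_overlap <- pairwise_overlap[0, , drop = FALSE]
  if (!is.null(drug_set)) {
    d <- if (inherits(drug_set, "gene_set")) drug_set else gene_set("drug", drug_set)
    g_drug <- build_graph(edges, seed_nodes = d)
    triple_symbols <- node_overlap(combined, g_drug)
    if (length(triple_symbols) == 0) {
      warn("triple_focus: empty overlap between the combined network and the drug set.")
    } else {
      triple_overlap <- rank_overlap_by_betweenness(triple_symbols, ct)
    }
  }

  summaries <- dplyr::bind_rows(
    summarize_network(g_a, a$name),
    summarize_network(g_b, b$name),
    summarize_network(combined, paste0(a$name, "-", b$name, " combined")),
    if (!is.null(g_drug)) summarize_network(g_drug, "drug_perturbed")
  )

  structure(
    list(
      summaries = summaries,
      centrality = ct,
      top_degree = top_degree,
      top_betweenness = top_betweenness,
      partition = partition,
      kept_communities = kept,
      enrichment = enrichment,
      shared_ab = shared_ab,
      pairwise_overlap = pairwise_overlap,
      triple_overlap = triple_overlap,
      graphs = list(a = g_a, b = g_b, combined = combined, drug = g_drug),
      meta = list(
        min_community_size = min_community_size,
        top_k = top_k,
        background = background,
        version = as.character(utils::packageVersion("triplefocus"))
      )
    ),
    class = "triple_focus_report"
  )
}

#' Rank shared symbols by combined-network betweenness
#'
#' The candidate-target table: one row per shared symbol with its degree
#' and betweenness centrality in the reference network, sorted by
#' betweenness descending with lexicographic tie-break.
#'
#' @param symbols Character vector of shared symbols; every one must be
#'   present in `table` (unknown symbols raise an error naming the first,
#'   which guards against un-normalized inputs).
#' @param table Centrality tibble from [centrality_table()].
#' @param top_k Optional row cap (default all).
#' @return Tibble (gene, degree_centrality, betweenness_centrality) in
#'   rank order.
#' @export
rank_overlap_by_betweenness <- function(symbols, table, top_k = Inf) {
  stopifnot(is.data.frame(table),
            all(c("gene", "degree_centrality", "betweenness_centrality") %in% names(table)))
  symbols <- unique(normalize_symbols(symbols))
  missing <- setdiff(symbols, table$gene)
  if (length(missing)) {
    abort(sprintf("rank_overlap_by_betweenness: symbol '%s' not in the centrality table.",
                  missing[1]),
          class = "triplefocus_invalid_input")
  }
  out <- table |>
    dplyr::filter(.data$gene %in% symbols) |>
    dplyr::arrange(dplyr::desc(.data$betweenness_centrality), .data$gene)
  head(out, top_k)
}

#' @export
print.triple_focus_report <- function(x, ...) {
  cat("<triple_focus_report>\n\nNetwork characteristics:\n")
  print(x$summaries)
  cat(sprintf("\nCommunities: %d detected (Q = %.4f), %d kept at min size %d\n",
              length(x$partition$communities), x$partition$q,
              length(x$kept_communities$communities), x$meta$min_community_size))
  cat(sprintf("Shared A/B genes: %d; triple-overlap rows: %d\n",
              length(x$shared_ab), nrow(x$triple_overlap)))
  if (nrow(x$triple_overlap)) {
    cat("\nTop candidate targets (by combined-network betweenness):\n")
    print(head(x$triple_overlap, x$meta$top_k))
  }
  invisible(x)
}

#' Tidy a triple-focusing report
#'
#' @param x A `triple_focus_report`.
#' @param table Which table to return: the ranked `"triple_overlap"`
#'   (default), `"pairwise_overlap"`, `"centrality"`, `"summaries"`,
#'   `"enrichment"` or `"communities"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.triple_focus_report <- function(x, table = c("triple_overlap", "pairwise_overlap",
                                                  "centrality", "summaries",
                                                  "enrichment", "communities"), ...) {
  table <- match.arg(table)
  switch(table,
    triple_overlap = x$triple_overlap,
    pairwise_overlap = x$pairwise_overlap,
    centrality = x$centrality,
    summaries = x$summaries,
    enrichment = if (is.null(x$enrichment)) {
      tibble::tibble()
    } else {
      x$enrichment
    },
    communities = tidy(x$partition)
  )
}

#' One-row summary of a triple-focusing report
#'
#' @param x A `triple_focus_report`.
#' @param ... Unused.
#' @return Tibble with combined-network size, modularity, community and
#'   overlap counts.
#' @export
glance.triple_focus_report <- function(x, ...) {
  comb <- x$graphs$combined
  tibble::tibble(
    nodes = comb$n,
    edges = comb$m,
    q = x$partition$q,
    n_communities = length(x$partition$communities),
    n_kept_communities = length(x$kept_communities$communities),
    n_shared_ab = length(x$shared_ab),
    n_triple_overlap = nrow(x$triple_overlap)
  )
}

#' Write all report tables to a directory
#'
#' Emits the TSV bundle: network summaries, per-node centralities, top-k
#' tables, community assignment, enrichment, and the pairwise and triple
#' overlap rankings.
#'
#' @param report A `triple_focus_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "triple_focus_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(tbl, name) {
    utils::write.table(tbl, file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  w(report$summaries, "network_summaries.tsv")
  w(report$centrality, "centrality.tsv")
  w(report$top_degree, "top_degree.tsv")
  w(report$top_betweenness, "top_betweenness.tsv")
  w(tidy(report$partition), "communities.tsv")
  if (!is.null(report$enrichment)) w(report$enrichment, "enrichment.tsv")
  w(report$pairwise_overlap, "pairwise_overlap.tsv")
  w(report$triple_overlap, "triple_overlap.tsv")
  invisible(dir)
}
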