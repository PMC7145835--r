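#' Centrality scatter plot
#'
#' Degree vs betweenness centrality for every node, the standard overview
#' of how influence concentrates in a few hub/gateway nodes; the top
#' `label_top` nodes by betweenness are labelled.
#'
#' @param table Centrality tibble from [centrality_table()].
#' @param label_top Number of top-betweenness nodes to label (default 10).
#' @return A ggplot object.
#' @export
plot_centrality <- function(table, label_top = 10) {
  stopifnot(is.data.frame(table),
            all(c("gene", "degree_centrality", "betweenness_centrality") %in% names(table)))
  lab <- rank_nodes(table, "betweenness_centrality", label_top)
  ggplot2::ggplot(table, ggplot2::aes(x = .data$degree_centrality,
                                      y = .data$betweenness_centrality)) +
    ggplot2::geom_point(alpha = 0.6, colour = "grey30") +
    ggplot2::geom_point(data = lab, colour = "firebrick") +
    ggplot2::geom_text(data = lab, ggplot2::aes(label = .data$gene),
                       vjust = -0.6, size = 3, colour = "firebrick") +
    ggplot2::labs(x = "Degree centrality", y = "Betweenness centrality") +
    ggplot2::theme_minimal()
}

#' @rdname plot_centrality
#' @param object A `triple_focus_report`.
#' @param ... Passed on to [plot_centrality()].
#' @export
autoplot.triple_focus_report <- function(object, ...) {
  p <- plot_centrality(object$centrality, ...)
  if (nrow(object$triple_overlap)) {
    p <- p + ggplot2::geom_point(
      data = object$triple_overlap, colour = "royalblue", shape = 17, size = 2.5)
  }
  p
}

#' Community size bar plot
#'
#' @param partition A `ppi_partition`.
#' @return A ggplot object.
#' @export
plot_communities <- function(partition) {
  stopifnot(inherits(partition, "ppi_partition"))
  sizes <- tibble::tibble(
    community = factor(seq_along(partition$communities)),
    size = lengths(partition$communities)
  )
  ggplot2::ggplot(sizes, ggplot2::aes(x = .data$community, y = .data$size)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Community", y = "Members") +
    ggplot2::theme_minimal()
}
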