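#' One-sided Fisher exact test for gene-set over-representation
#'
#' Upper hypergeometric tail: with a background of N genes of which K are
#' in the pathway and a community of s genes of which k hit the pathway,
#' p = sum_{i >= k} C(K, i) C(N - K, s - i) / C(N, s). Evaluated exactly on
#' the log scale via [stats::phyper()]. This is the enrichment direction
#' only (over-representation), not the two-sided test.
#'
#' @param k Observed overlap (0 <= k <= min(K, s)).
#' @param K Pathway size within the background.
#' @param s Community (query set) size within the background.
#' @param N Background (universe) size.
#' @return The one-sided p-value; exactly 1 when k = 0.
#' @export
#' @examples
#' fisher_exact_greater(5, 5, 5, 10)  # 1 / choose(10, 5)
fisher_exact_greater <- function(k, K, s, N) {
  stopifnot(length(k) == 1, length(K) == 1, length(s) == 1, length(N) == 1)
  if (k < 0 || K < 0 || s < 0 || N < 1 || K > N || s > N || k > min(K, s)) {
    abort(sprintf("fisher_exact_greater: invalid counts k=%s K=%s s=%s N=%s.", k, K, s, N),
          class = "triplefocus_contract_error")
  }
  if (k == 0) return(1)
  phyper(k - 1, K, N - K, s, lower.tail = FALSE)
}

#' Benjamini--Hochberg FDR adjustment
#'
#' Step-up procedure: on the sorted p-values, q_(i) = min over j >= i of
#' m p_(j) / j, mapped back to input order and capped at 1. Delegates to
#' [stats::p.adjust()] after checking every p lies in (0, 1].
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Adjusted q-values in input order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    abort("bh_adjust: p-values must lie in (0, 1].",
          class = "triplefocus_contract_error")
  }
  p.adjust(p, method = "BH")
}

#' Community-to-pathway enrichment
#'
#' Tests every (community, pathway) pair for over-representation of the
#' community's members among the pathway's genes, within a fixed
#' background. Pathways and communities are intersected with the
#' background first; pairs with zero overlap are suppressed before
#' adjustment, and BH is applied jointly across all emitted rows (one
#' call, not per community).
#'
#' @param partition A `ppi_partition` (typically after
#'   [filter_communities()]).
#' @param pathways A `pathway_collection`.
#' @param background [gene_set], character vector or `ppi_graph` defining
#'   the universe; must contain every community member.
#' @return Tibble with columns `community`, `pathway`, `source_id`, `k`
#'   (overlap), `K` (pathway size in background), `s` (community size),
#'   `N` (background size), `p`, `q`; sorted by (community, q, p, pathway).
#' @export
enrich_communities <- function(partition, pathways, background) {
  stopifnot(inherits(partition, "ppi_partition"), is.data.frame(pathways))
  bg <- as_members(background, "background")
  if (length(bg) == 0) {
    abort("enrich_communities: empty background.", class = "triplefocus_invalid_input")
  }
  comm_members <- lapply(partition$communities, intersect, y = bg)
  not_in_bg <- sum(lengths(partition$communities)) - sum(lengths(comm_members))
  if (not_in_bg > 0) {
    abort(sprintf("enrich_communities: %d community member(s) missing from the background.",
                  not_in_bg),
          class = "triplefocus_contract_error")
  }
  pwy_members <- lapply(pathways$genes, intersect, y = bg)
  N <- length(bg)
  rows <- purrr::map_dfr(seq_along(comm_members), function(ci) {
    cm <- comm_members[[ci]]
    if (length(cm) == 0) return(NULL)
    purrr::map_dfr(seq_along(pwy_members), function(pi) {
      pw <- pwy_members[[pi]]
      k <- length(intersect(cm, pw))
      if (k == 0) return(NULL)
      tibble::tibble(
        community = ci,
        pathway = pathways$pathway[pi],
        source_id = pathways$source_id[pi],
        k = k, K = length(pw), s = length(cm), N = N,
        p = fisher_exact_greater(k, length(pw), length(cm), N)
      )
    })
  })
  if (nrow(rows) == 0) {
    return(tibble::tibble(community = integer(), pathway = character(),
                          source_id = character(), k = integer(), K = integer(),
                          s = integer(), N = integer(), p = numeric(), q = numeric()))
  }
  rows$q <- bh_adjust(rows$p)
  dplyr::arrange(rows, .data$community, .data$q, .data$p, .data$pathway)
}
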