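#' Truncate a value toward zero at a number of significant figures
#'
#' Reporting convention used for network summary tables: values are cut, not
#' rounded, so 0.10699 becomes 0.106 and 0.011955 becomes 0.0119. Full
#' precision is always kept internally; this is a display/comparison helper.
#'
#' @param x Numeric vector.
#' @param digits Significant figures to keep (default 3).
#' @return Numeric vector truncated toward zero.
#' @export
#' @examples
#' truncate_signif(c(0.10699, 0.011955))
truncate_signif <- function(x, digits = 3) {
  stopifnot(is.numeric(x), digits >= 1)
  out <- x
  nz <- is.finite(x) & x != 0
  e <- floor(log10(abs(x[nz])))
  f <- 10^(e - digits + 1)
  # tiny relative nudge so values stored as 0.1059999... truncate as printed
  out[nz] <- trunc(x[nz] / f * (1 + 1e-12)) * f
  out
}

#' Expected mean normalized degree centrality from node and edge counts
#'
#' Closed-form identity: the mean over all nodes of deg(v)/(n-1) equals
#' 2m / (n (n - 1)). Used to check published network characteristic rows
#' against their own node and edge counts.
#'
#' @param n Node count (>= 2).
#' @param m Edge count.
#' @return The mean normalized degree centrality, a value in \[0, 1\].
#' @export
#' @examples
#' expected_mean_degree_centrality(486, 1409)
expected_mean_degree_centrality <- function(n, m) {
  stopifnot(n >= 2, m >= 0)
  2 * m / (n * (n - 1))
}

#' Normalized mutual information between two labelings
#'
#' Scores agreement between a detected community assignment and a planted
#' block structure. 1 means identical partitions (up to label permutation),
#' 0 means independence. Both labelings must cover the same items.
#'
#' @param a,b Vectors of labels of equal length (names are ignored; order
#'   aligns the two).
#' @return NMI in \[0, 1\]; defined as 1 when both partitions are trivial
#'   (single cluster each).
#' @export
partition_nmi <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  n <- length(a)
  tab <- table(a, b)
  pij <- tab / n
  pi. <- rowSums(pij)
  p.j <- colSums(pij)
  h <- function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  }
  ha <- h(pi.)
  hb <- h(p.j)
  if (ha == 0 && hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  ex <- outer(pi., p.j)
  keep <- pij > 0
  mi <- sum(pij[keep] * log(pij[keep] / ex[keep]))
  # arithmetic-mean normalization (the common community-comparison convention)
  2 * mi / (ha + hb)
}

# shared symbol normalization: trim whitespace, upper-case
normalize_symbols <- function(x) {
  toupper(trimws(x))
}
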