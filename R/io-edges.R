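#' Read a STRING-dialect interaction edge list
#'
#' Expects a tab-separated file whose first three columns are
#' `protein_a`, `protein_b`, `combined_score` with scores on the STRING
#' 0--1000 integer scale. A header row is detected by a non-numeric third
#' field and skipped. Parsing applies, in order: symbol normalization
#' (trim + upper-case), self-loop removal (counted, reported as a message),
#' collapse of duplicate unordered pairs keeping the maximum score, and the
#' confidence filter `score > min_confidence * 1000` (strict, so 400 does
#' not pass the default 0.4 medium-confidence cutoff).
#'
#' @param path Path to the TSV file.
#' @param min_confidence Confidence threshold on the 0--1 scale; edges must
#'   score strictly above `min_confidence * 1000`. Default 0.4 (STRING
#'   medium confidence).
#' @return A tibble of interaction records with columns `node_a`, `node_b`
#'   (lexicographically ordered within each row), `score`; rows sorted by
#'   (node_a, node_b).
#' @export
read_edge_list <- function(path, min_confidence = 0.4) {
  if (!file.exists(path)) {
    abort(sprintf("Edge list file not found: %s", path), class = "triplefocus_io_error")
  }
  stopifnot(is.numeric(min_confidence), min_confidence >= 0, min_confidence <= 1)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0) return(empty_edge_tbl())

  fields <- strsplit(lines, "\t", fixed = TRUE)
  # header: optional, detected by a non-numeric third field on the first row
  first <- fields[[1]]
  if (length(first) >= 3 && is.na(suppressWarnings(as.numeric(trimws(first[3]))))) {
    fields <- fields[-1]
    line_no <- line_no[-1]
  }
  if (length(fields) == 0) return(empty_edge_tbl())

  nf <- lengths(fields)
  bad <- which(nf < 3)
  if (length(bad)) {
    abort(sprintf("Malformed edge row at line %d: expected >= 3 tab-separated fields, got %d.",
                  line_no[bad[1]], nf[bad[1]]),
          class = "triplefocus_parse_error")
  }
  a <- normalize_symbols(vapply(fields, `[[`, "", 1))
  b <- normalize_symbols(vapply(fields, `[[`, "", 2))
  score_raw <- trimws(vapply(fields, `[[`, "", 3))
  score <- suppressWarnings(as.numeric(score_raw))
  bad <- which(is.na(score) | score != floor(score))
  if (length(bad)) {
    abort(sprintf("Malformed edge row at line %d: combined_score '%s' is not an integer.",
                  line_no[bad[1]], score_raw[bad[1]]),
          class = "triplefocus_parse_error")
  }
  bad <- which(score < 0 | score > 1000)
  if (length(bad)) {
    abort(sprintf("Edge row at line %d: combined_score %d outside 0-1000.",
                  line_no[bad[1]], as.integer(score[bad[1]])),
          class = "triplefocus_parse_error")
  }
  bad <- which(!nzchar(a) | !nzchar(b))
  if (length(bad)) {
    abort(sprintf("Edge row at line %d: empty gene symbol.", line_no[bad[1]]),
          class = "triplefocus_parse_error")
  }

  n_self <- sum(a == b)
  if (n_self > 0) {
    inform(sprintf("read_edge_list: dropped %d self-loop(s) in %s", n_self, basename(path)))
  }
  keep <- a != b
  tbl <- tibble::tibble(
    node_a = pmin(a[keep], b[keep]),
    node_b = pmax(a[keep], b[keep]),
    score = as.integer(score[keep])
  )
  tbl <- collapse_duplicate_pairs(tbl) |>
    dplyr::filter(.data$score > min_confidence * 1000)
  tbl
}

empty_edge_tbl <- function() {
  tibble::tibble(node_a = character(), node_b = character(), score = integer())
}

# collapse duplicate unordered pairs keeping the max score (empty-safe)
collapse_duplicate_pairs <- function(tbl) {
  if (nrow(tbl) == 0) return(dplyr::arrange(tbl, .data$node_a, .data$node_b))
  tbl |>
    dplyr::group_by(.data$node_a, .data$node_b) |>
    dplyr::summarise(score = max(.data$score), .groups = "drop") |>
    dplyr::arrange(.data$node_a, .data$node_b)
}

# validate an in-memory interaction table (used by generators/round-trips)
as_edge_tbl <- function(edges) {
  if (!is.data.frame(edges) || !all(c("node_a", "node_b") %in% names(edges))) {
    abort("`edges` must be a data frame with columns node_a, node_b (and optionally score).",
          class = "triplefocus_invalid_input")
  }
  a <- normalize_symbols(edges$node_a)
  b <- normalize_symbols(edges$node_b)
  score <- if ("score" %in% names(edges)) as.integer(edges$score) else rep(1000L, length(a))
  keep <- a != b
  collapse_duplicate_pairs(
    tibble::tibble(node_a = pmin(a, b)[keep], node_b = pmax(a, b)[keep],
                   score = score[keep]))
}

#' Write an interaction edge list as STRING-dialect TSV
#'
#' @param edges Tibble with columns `node_a`, `node_b`, `score`.
#' @param path Output path.
#' @param header Write a `protein_a/protein_b/combined_score` header row
#'   (default TRUE).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path, header = TRUE) {
  edges <- as_edge_tbl(edges)
  body <- sprintf("%s\t%s\t%d", edges$node_a, edges$node_b, edges$score)
  if (header) body <- c("protein_a\tprotein_b\tcombined_score", body)
  writeLines(body, path)
  invisible(path)
}
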