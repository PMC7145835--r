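#' Read a GMT pathway collection
#'
#' Standard tab-separated gene-set format: one pathway per line with fields
#' name, source id / description, then member symbols. Members are
#' normalized (trim, upper-case) and de-duplicated.
#'
#' @param path Path to the GMT file.
#' @return A `pathway_collection`: a tibble with columns `pathway`,
#'   `source_id` and a list-column `genes` of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("GMT file not found: %s", path), class = "triplefocus_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0) return(empty_pathway_collection())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 3)
  if (length(bad)) {
    abort(sprintf("Malformed GMT line %d: expected >= 3 tab-separated fields, got %d.",
                  line_no[bad[1]], nf[bad[1]]),
          class = "triplefocus_parse_error")
  }
  nm <- trimws(vapply(fields, `[[`, "", 1))
  if (anyDuplicated(nm)) {
    abort(sprintf("Duplicate pathway name in GMT: '%s'.", nm[duplicated(nm)][1]),
          class = "triplefocus_parse_error")
  }
  genes <- lapply(fields, function(f) sort(unique(normalize_symbols(f[-(1:2)]))))
  if (any(lengths(genes) == 0)) {
    abort(sprintf("Empty pathway '%s' in GMT.", nm[which(lengths(genes) == 0)[1]]),
          class = "triplefocus_parse_error")
  }
  new_pathway_collection(
    pathway = nm,
    source_id = trimws(vapply(fields, `[[`, "", 2)),
    genes = genes
  )
}

new_pathway_collection <- function(pathway, source_id, genes) {
  out <- tibble::tibble(pathway = pathway, source_id = source_id, genes = genes)
  class(out) <- c("pathway_collection", class(out))
  out
}

empty_pathway_collection <- function() {
  new_pathway_collection(character(), character(), list())
}

#' Write a pathway collection as GMT
#'
#' @param pathways A `pathway_collection` tibble as returned by [read_gmt()]
#'   or [generate_pathways()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(pathways, path) {
  stopifnot(is.data.frame(pathways),
            all(c("pathway", "source_id", "genes") %in% names(pathways)))
  lines <- purrr::pmap_chr(
    pathways[c("pathway", "source_id", "genes")],
    function(pathway, source_id, genes) {
      paste(c(pathway, source_id, sort(unique(genes))), collapse = "\t")
    }
  )
  writeLines(lines, path)
  invisible(path)
}
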