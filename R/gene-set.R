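#' Construct a gene set
#'
#' A named collection of unique gene symbols (a disease gene list or a
#' drug-perturbation list). Symbols are whitespace-trimmed, upper-cased and
#' de-duplicated; the stored member vector is sorted for determinism.
#'
#' @param name Non-empty label for the set.
#' @param members Character vector of gene symbols.
#' @return A `gene_set` object.
#' @export
#' @examples
#' gene_set("demo", c("sema3a", "SEMA3A", " tusc3 "))
gene_set <- function(name, members) {
  if (!is.character(name) || length(name) != 1 || !nzchar(trimws(name))) {
    abort("`name` must be a single non-empty string.", class = "triplefocus_invalid_input")
  }
  members <- normalize_symbols(as.character(members))
  members <- members[nzchar(members)]
  structure(
    list(name = trimws(name), members = sort(unique(members))),
    class = "gene_set"
  )
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes\n", x$name, length(x$members)))
  if (length(x$members)) {
    shown <- head(x$members, 8)
    cat(" ", paste(shown, collapse = ", "),
        if (length(x$members) > 8) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$members)

# accept a gene_set, a character vector, or a ppi_graph node set
as_members <- function(x, arg = "x") {
  if (inherits(x, "gene_set")) return(x$members)
  if (inherits(x, "ppi_graph")) return(x$nodes)
  if (is.character(x)) return(sort(unique(normalize_symbols(x))))
  abort(sprintf("`%s` must be a gene_set, character vector, or ppi_graph.", arg),
        class = "triplefocus_invalid_input")
}

#' Read a gene list file
#'
#' One symbol per line; lines starting with `#` are comments and blank lines
#' are skipped. Symbols are trimmed, upper-cased and de-duplicated; the
#' number of duplicates dropped is reported as a message.
#'
#' @param path Path to the text file.
#' @param name Label for the resulting set (defaults to the file name).
#' @return A [gene_set].
#' @export
read_gene_list <- function(path, name = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("Gene list file not found: %s", path), class = "triplefocus_io_error")
  }
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  symbols <- normalize_symbols(lines)
  n_dup <- length(symbols) - length(unique(symbols))
  if (n_dup > 0) {
    inform(sprintf("read_gene_list: dropped %d duplicate symbol(s) in %s", n_dup, basename(path)))
  }
  if (length(symbols) == 0) {
    abort(sprintf("Gene list is empty after parsing: %s", path),
          class = "triplefocus_empty_input")
  }
  gene_set(name, symbols)
}

#' Write a gene list file
#'
#' @param x A [gene_set] or character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(x, path) {
  writeLines(as_members(x), path)
  invisible(path)
}
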