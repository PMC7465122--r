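#' Read a gene-by-sample expression matrix from TSV
#'
#' The file must have gene identifiers in the first column and one column
#' per sample, with a header row of sample IDs.
#'
#' @param path path to a tab-delimited file.
#' @return numeric matrix, genes in rows, samples in columns.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}

#' Write a gene-by-sample expression matrix to TSV
#'
#' @param mat numeric matrix with gene rownames and sample colnames.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  write_tsv(df, path)
}

#' Read a sample sheet
#'
#' Expected columns: `sample_id`, `subject_id`, `condition`
#' (`tumor`/`normal`) and `dataset_id`.
#'
#' @param path path to a tab-delimited sample sheet.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  ss <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  need <- c("sample_id", "subject_id", "condition")
  miss <- setdiff(need, names(ss))
  if (length(miss) > 0)
    stop("sample sheet is missing columns: ", paste(miss, collapse = ", "))
  ss
}

#' Read a regulatory or interaction edge table
#'
#' @param path path to a tab-delimited edge table.
#' @return data.frame with the file's columns.
#' @export
read_edge_table <- function(path) {
  utils::read.delim(path, check.names = FALSE)
}

#' Read a per-subject survival table
#'
#' Expected columns: `subject_id`, `time_months`, `event`, then one
#' expression column per gene.
#'
#' @param path path to a tab-delimited survival table.
#' @return data.frame.
#' @export
read_survival_table <- function(path) {
  utils::read.delim(path, check.names = FALSE)
}

#' Read a one-identifier-per-line screening list
#'
#' @param path path to a plain-text file.
#' @return character vector with blank lines removed.
#' @export
read_screen_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x)]
}

#' Read a gene-set library in GMT format
#'
#' Standard two-header-column GMT: term name, description, then the member
#' genes, all tab-separated.
#'
#' @param path path to a `.gmt` file.
#' @param label library label; defaults to the file name.
#' @return a `gene_set_library`: list with `terms` (named list of character
#'   vectors), `description` (named character) and `label`.
#' @export
read_gmt <- function(path, label = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 3
  if (any(bad)) stop("malformed GMT line(s): ", which(bad)[1])
  terms <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(terms) <- vapply(parts, `[[`, character(1), 1)
  desc <- vapply(parts, `[[`, character(1), 2)
  names(desc) <- names(terms)
  gene_set_library(terms, description = desc, label = label)
}

#' Construct a gene-set library object
#'
#' @param terms named list of character vectors (term -> member genes).
#' @param description optional named character vector of term descriptions.
#' @param label library label.
#' @return a `gene_set_library` object.
#' @export
gene_set_library <- function(terms, description = NULL, label = "library") {
  stopifnot(is.list(terms), !is.null(names(terms)))
  if (any(vapply(terms, length, integer(1)) == 0))
    stop("gene-set terms must be nonempty")
  if (is.null(description)) {
    description <- stats::setNames(names(terms), names(terms))
  }
  structure(list(terms = terms, description = description, label = label),
            class = "gene_set_library")
}

#' Write a gene-set library to GMT
#'
#' @param library a `gene_set_library` (or named list of character vectors).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gmt <- function(library, path) {
  if (!inherits(library, "gene_set_library")) library <- gene_set_library(library)
  lines <- vapply(names(library$terms), function(nm) {
    paste(c(nm, library$description[[nm]], library$terms[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
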