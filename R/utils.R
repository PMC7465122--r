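`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalise a miRNA identifier for cross-species matching
#'
#' Strips the species prefix (`hsa-`, `mmu-`) and lower-cases the rest, so
#' that a human miRNA and its mouse ortholog compare equal by name.
#'
#' @param x character vector of miRNA identifiers.
#' @return character vector of normalised names.
#' @export
#' @examples
#' normalize_mirna(c("hsa-miR-20b-5p", "mmu-miR-20b-5p"))
normalize_mirna <- function(x) {
  tolower(sub("^(hsa|mmu)-", "", as.character(x)))
}

#' Normalise a binding-region annotation
#'
#' Removes punctuation (apostrophes, typographic primes, hyphens) and
#' upper-cases, so that "3'UTR", "3UTR" and the typographic variant all
#' normalise to "3UTR".
#'
#' @param x character vector of region labels.
#' @return character vector of normalised labels.
#' @export
normalize_region <- function(x) {
  toupper(gsub("[^0-9A-Za-z]", "", as.character(x)))
}

# fixed module colour palette; largest module gets the first colour
module_colors <- function(n) {
  pal <- c("turquoise", "blue", "brown", "yellow", "green", "red", "black",
           "pink", "magenta", "purple", "greenyellow", "tan", "salmon",
           "cyan", "midnightblue", "lightcyan", "grey60", "lightgreen",
           "lightyellow", "royalblue", "darkred", "darkgreen", "darkturquoise",
           "darkgrey", "orange", "darkorange", "white", "skyblue",
           "saddlebrown", "steelblue")
  if (n <= length(pal)) pal[seq_len(n)] else c(pal, paste0("module", seq_len(n - length(pal))))
}

write_tsv <- function(x, path, row_names = FALSE) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = row_names, col.names = TRUE)
  invisible(path)
}
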