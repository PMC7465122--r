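#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test per term: with universe size N, term size
#' m (after intersecting with the universe) and query size q (likewise),
#' p = P(X >= overlap). BH adjustment is applied within the library.
#'
#' @param query_genes character vector of query genes.
#' @param library a `gene_set_library` (or plain named list of character
#'   vectors).
#' @param universe optional background; defaults to the union of all term
#'   genes. Enrichment p-values depend strongly on this choice.
#' @param alpha significance threshold on the BH-adjusted p (default 0.001,
#'   strict); stored for downstream hub calling.
#' @return data.frame (class `enrichment_result`) with per-term overlap
#'   counts, sizes, `p`, `p_bh`, `significant` and the overlapping genes;
#'   the overlap gene sets are attached as attribute `overlap_sets`.
#' @export
enrich <- function(query_genes, library, universe = NULL, alpha = 0.001) {
  if (!inherits(library, "gene_set_library")) library <- gene_set_library(library)
  terms <- library$terms
  if (is.null(universe)) universe <- sort(unique(unlist(terms)))
  query_genes <- unique(query_genes)
  if (length(query_genes) == 0) stop("query gene set is empty")
  q <- intersect(query_genes, universe)
  if (length(q) == 0) stop("query genes are disjoint from the universe")
  N <- length(universe)
  ov_sets <- lapply(terms, function(tg) sort(intersect(intersect(tg, universe), q)))
  m <- vapply(terms, function(tg) length(intersect(tg, universe)), integer(1))
  k <- vapply(ov_sets, length, integer(1))
  p <- stats::phyper(k - 1, m, N - m, length(q), lower.tail = FALSE)
  out <- data.frame(term = names(terms), library = library$label,
                    overlap = k, term_size = m, query_size = length(q),
                    universe_size = N, p = p, p_bh = bh_adjust(p),
                    genes = vapply(ov_sets, paste, character(1), collapse = ","),
                    row.names = NULL)
  out$significant <- out$p_bh < alpha
  out <- out[order(out$p, out$term), ]
  rownames(out) <- NULL
  attr(out, "overlap_sets") <- ov_sets
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Hub genes from significant enrichment terms
#'
#' The hub set is the intersection, over every significantly enriched term
#' from every supplied library, of that term's overlap with the query. An
#' empty intersection is allowed and reported; no significant term at all
#' yields an empty set with a warning.
#'
#' @param results an `enrichment_result` or list of them (one per library).
#' @param alpha significance threshold on BH-adjusted p (default 0.001,
#'   strict).
#' @return sorted character vector of hub genes.
#' @export
hub_genes <- function(results, alpha = 0.001) {
  if (inherits(results, "enrichment_result")) results <- list(results)
  sets <- list()
  for (res in results) {
    sig <- !is.na(res$p_bh) & res$p_bh < alpha
    if (!any(sig)) next
    gs <- strsplit(res$genes[sig], ",", fixed = TRUE)
    sets <- c(sets, gs)
  }
  if (length(sets) == 0) {
    warning("no significantly enriched terms; hub set is empty")
    return(character(0))
  }
  sort(Reduce(intersect, sets))
}
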