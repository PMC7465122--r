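regulatory_types <- c("miRNA-gene", "TF-gene", "miRNA-TF")

check_edge_table <- function(edges) {
  need <- c("source", "target", "type")
  miss <- setdiff(need, names(edges))
  if (length(miss) > 0)
    stop("edge table is missing columns: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(edges$type), regulatory_types)
  if (length(bad) > 0) stop("unknown edge type(s): ", paste(bad, collapse = ", "))
  if (!"score" %in% names(edges)) edges$score <- NA_real_
  if (!"binding_region" %in% names(edges)) edges$binding_region <- NA_character_
  if (!"p_value" %in% names(edges)) edges$p_value <- NA_real_
  edges
}

#' Filter regulatory edges at the confidence thresholds
#'
#' miRNA edges (miRNA-gene and miRNA-TF) are kept iff their target-site
#' score is strictly above `mirna_score` and the binding region normalises
#' to "3UTR"; TF-gene edges are kept iff their integrated rank p-value is
#' strictly below `tf_p`. Duplicate (source, target, type) rows collapse to
#' one.
#'
#' @param edges data.frame with columns `source`, `target`, `type`
#'   (one of "miRNA-gene", "TF-gene", "miRNA-TF"), `score`,
#'   `binding_region`, `p_value`.
#' @param mirna_score miRNA target-score threshold (default 0.95, strict).
#' @param tf_p TF-gene p-value threshold (default 0.001, strict).
#' @return the filtered edge table.
#' @export
filter_regulatory_edges <- function(edges, mirna_score = 0.95, tf_p = 0.001) {
  edges <- check_edge_table(edges)
  if (nrow(edges) == 0) return(edges)
  is_mirna <- edges$type %in% c("miRNA-gene", "miRNA-TF")
  keep <- logical(nrow(edges))
  keep[is_mirna] <- !is.na(edges$score[is_mirna]) &
    edges$score[is_mirna] > mirna_score &
    normalize_region(edges$binding_region[is_mirna]) == "3UTR"
  keep[!is_mirna] <- !is.na(edges$p_value[!is_mirna]) &
    edges$p_value[!is_mirna] < tf_p
  out <- edges[keep, , drop = FALSE]
  out <- out[!duplicated(out[, c("source", "target", "type")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Two-tier validation screen of regulators
#'
#' Tier 1 is a literature whitelist of miRNAs and TFs. Tier 2 keeps the
#' tier-1 miRNAs that also appear, at the same confidence thresholds, in
#' mouse target tables (name-matched after stripping species prefixes), so
#' surviving miRNAs are human-mouse conserved. TFs pass on tier-1
#' membership alone. Edges are restricted to surviving regulators (and, for
#' miRNA-TF edges, to surviving TF targets).
#'
#' @param edges filtered human edge table.
#' @param tier1 character vector of literature-supported miRNAs and TFs.
#' @param mouse_tables data.frame (or list of them) of mouse regulatory
#'   edges; filtered here with the same thresholds.
#' @param conserve_targets `"all"` checks mouse conservation against both
#'   miRNA-gene and miRNA-TF mouse edges; `"genes"` against miRNA-gene
#'   edges only.
#' @param mirna_score,tf_p thresholds passed to [filter_regulatory_edges()]
#'   for the mouse tables.
#' @return the screened edge table.
#' @export
two_tier_screen <- function(edges, tier1, mouse_tables,
                            conserve_targets = c("all", "genes"),
                            mirna_score = 0.95, tf_p = 0.001) {
  conserve_targets <- match.arg(conserve_targets)
  edges <- check_edge_table(edges)
  if (length(tier1) == 0) {
    warning("empty tier-1 list; all edges dropped")
    return(edges[0, , drop = FALSE])
  }
  t1_mirna <- normalize_mirna(tier1)
  t1_tf <- toupper(tier1)
  if (is.data.frame(mouse_tables)) mouse_tables <- list(mouse_tables)
  mouse <- do.call(rbind, lapply(mouse_tables, check_edge_table))
  mouse <- filter_regulatory_edges(mouse, mirna_score = mirna_score, tf_p = tf_p)
  mouse_types <- if (conserve_targets == "all") c("miRNA-gene", "miRNA-TF") else "miRNA-gene"
  mouse_mirnas <- normalize_mirna(mouse$source[mouse$type %in% mouse_types])
  tier2_ok <- function(mir) {
    nm <- normalize_mirna(mir)
    nm %in% t1_mirna & nm %in% mouse_mirnas
  }
  tf_ok <- function(tf) toupper(tf) %in% t1_tf
  keep <- logical(nrow(edges))
  mg <- edges$type == "miRNA-gene"
  mt <- edges$type == "miRNA-TF"
  tg <- edges$type == "TF-gene"
  keep[mg] <- tier2_ok(edges$source[mg])
  keep[mt] <- tier2_ok(edges$source[mt]) & tf_ok(edges$target[mt])
  keep[tg] <- tf_ok(edges$source[tg])
  out <- edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble the typed miRNA-TF-gene regulatory network
#'
#' Merges the (already filtered/screened) edge tables into one simple typed
#' digraph, infers node roles from the edge types, and reports per-type
#' edge counts plus per-node degrees over the merged network.
#'
#' @param edges edge table with columns `source`, `target`, `type`.
#' @return list of class `ffl_network` with `nodes` (node, role, degree),
#'   `edges`, `n_nodes`, `n_edges` and `edge_counts` per type.
#' @export
assemble_ffl_network <- function(edges) {
  edges <- check_edge_table(edges)
  edges <- edges[!duplicated(edges[, c("source", "target", "type")]), , drop = FALSE]
  if (nrow(edges) == 0) {
    return(structure(list(nodes = data.frame(node = character(0),
                                             role = character(0),
                                             degree = integer(0)),
                          edges = edges, n_nodes = 0L, n_edges = 0L,
                          edge_counts = stats::setNames(integer(3), regulatory_types)),
                     class = "ffl_network"))
  }
  roles <- list(
    miRNA = unique(edges$source[edges$type %in% c("miRNA-gene", "miRNA-TF")]),
    TF = unique(c(edges$source[edges$type == "TF-gene"],
                  edges$target[edges$type == "miRNA-TF"])),
    gene = unique(edges$target[edges$type %in% c("miRNA-gene", "TF-gene")]))
  all_nodes <- unique(c(edges$source, edges$target))
  role_of <- stats::setNames(rep(NA_character_, length(all_nodes)), all_nodes)
  for (r in names(roles)) {
    clash <- roles[[r]][!is.na(role_of[roles[[r]]]) & role_of[roles[[r]]] != r]
    if (length(clash) > 0)
      stop("node(s) with conflicting roles: ", paste(clash, collapse = ", "))
    role_of[roles[[r]]] <- r
  }
  simple <- unique(edges[, c("source", "target")])
  deg <- table(c(simple$source, simple$target))
  nodes <- data.frame(node = all_nodes, role = unname(role_of[all_nodes]),
                      degree = as.integer(deg[all_nodes]), row.names = NULL)
  nodes <- nodes[order(nodes$role, nodes$node), ]
  rownames(nodes) <- NULL
  counts <- stats::setNames(integer(3), regulatory_types)
  tc <- table(edges$type)
  counts[names(tc)] <- as.integer(tc)
  structure(list(nodes = nodes, edges = edges,
                 n_nodes = nrow(nodes), n_edges = nrow(simple),
                 edge_counts = counts),
            class = "ffl_network")
}

#' Enumerate closed 3-node feed-forward loops and composite motifs
#'
#' A closed FFL is a triple (miRNA m, TF t, gene g) with edges m->t, t->g
#' and m->g all present. FFLs sharing the same miRNA and gene are merged
#' into composite instances (one miRNA, one or more TFs, one gene). Each
#' instance's order statistic is the sum of merged-network degrees of its
#' constituent nodes.
#'
#' @param network an `ffl_network`.
#' @return list of motif instances sorted by decreasing order, each with
#'   `mirna`, `tfs`, `gene`, `order`, `n_tfs` and `edges`.
#' @export
ffl_motifs <- function(network) {
  stopifnot(inherits(network, "ffl_network"))
  e <- network$edges
  has <- function(type) {
    sel <- e[e$type == type, c("source", "target")]
    paste(sel$source, sel$target, sep = "\r")
  }
  mt <- has("miRNA-TF")
  tg <- has("TF-gene")
  mg <- has("miRNA-gene")
  mirnas <- network$nodes$node[network$nodes$role == "miRNA"]
  tfs <- network$nodes$node[network$nodes$role == "TF"]
  genes <- network$nodes$node[network$nodes$role == "gene"]
  deg <- stats::setNames(network$nodes$degree, network$nodes$node)
  hits <- list()
  for (m in mirnas) for (t in tfs) for (g in genes) {
    if (paste(m, t, sep = "\r") %in% mt &&
        paste(t, g, sep = "\r") %in% tg &&
        paste(m, g, sep = "\r") %in% mg) {
      hits[[length(hits) + 1]] <- c(m, t, g)
    }
  }
  if (length(hits) == 0) return(list())
  df <- as.data.frame(do.call(rbind, hits), stringsAsFactors = FALSE)
  names(df) <- c("mirna", "tf", "gene")
  keyed <- split(df, paste(df$mirna, df$gene, sep = "\r"))
  inst <- lapply(keyed, function(d) {
    ts <- sort(unique(d$tf))
    ed <- rbind(
      data.frame(source = d$mirna[1], target = d$gene[1], type = "miRNA-gene"),
      data.frame(source = d$mirna[1], target = ts, type = "miRNA-TF"),
      data.frame(source = ts, target = d$gene[1], type = "TF-gene"))
    list(mirna = d$mirna[1], tfs = ts, gene = d$gene[1],
         n_tfs = length(ts),
         order = unname(sum(deg[c(d$mirna[1], ts, d$gene[1])])),
         edges = ed)
  })
  ord <- order(-vapply(inst, `[[`, numeric(1), "order"),
               -vapply(inst, `[[`, numeric(1), "n_tfs"),
               vapply(inst, function(x) paste(x$mirna, x$gene, paste(x$tfs, collapse = ",")),
                      character(1)))
  unname(inst[ord])
}

#' Highest-order network motif
#'
#' Returns the composite FFL instance with the largest summed node degree;
#' ties are broken by more TFs, then by lexicographic node names. `NULL`
#' (with a message) when the network contains no closed FFL.
#'
#' @param network an `ffl_network`.
#' @return a motif instance (see [ffl_motifs()]) or `NULL`.
#' @export
highest_order_motif <- function(network) {
  m <- ffl_motifs(network)
  if (length(m) == 0) {
    message("no closed 3-node feed-forward loop in the network")
    return(NULL)
  }
  m[[1]]
}

#' Write an ffl_network in SIF format
#'
#' @param network an `ffl_network`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_sif <- function(network, path) {
  e <- network$edges
  writeLines(paste(e$source, e$type, e$target, sep = "\t"), path)
  invisible(path)
}

#' Synthetic reconstruction of the published regulatory summary table
#'
#' The published network summary reports only marginal counts: 19
#' miRNA-gene, 25 TF-gene and 22 miRNA-TF edges over 11 miRNAs, 5 hub genes
#' and 5 TFs (21 nodes, 66 edges in the merged network), with per-node
#' degrees for the named regulators. This function returns a deterministic
#' synthetic edge set honouring every one of those marginals (BIRC5
#' targeted by 8 miRNAs; CCNB1, KIF11 and KIF4A by 3; miR-20b-5p targeting
#' 4 hub genes; HMGA2 and E2F7 targeted by 9 and 7 miRNAs; a complete
#' TF-gene block). The individual pairs are NOT the published ones, which
#' were never printed; unnamed regulators carry clearly synthetic
#' identifiers.
#'
#' @return list with data.frames `mirna_gene`, `tf_gene`, `mirna_tf`, all
#'   carrying filter-passing scores/regions/p-values.
#' @export
table2_tables <- function() {
  mirnas <- c("hsa-miR-20b-5p", sprintf("hsa-miR-9%02d-5p", 1:10))
  genes <- c("BIRC5", "CCNB1", "KIF11", "KIF4A", "KIF20A")
  tfs <- c("HMGA2", "E2F7", "TFA", "TFB", "TFC")
  mg <- rbind(
    data.frame(source = mirnas[1:8], target = "BIRC5"),
    data.frame(source = mirnas[c(1, 9, 10)], target = "CCNB1"),
    data.frame(source = mirnas[c(1, 9, 11)], target = "KIF11"),
    data.frame(source = mirnas[c(1, 10, 11)], target = "KIF4A"),
    data.frame(source = mirnas[c(2, 3)], target = "KIF20A"))
  mg$type <- "miRNA-gene"
  mt <- rbind(
    data.frame(source = mirnas[1:9], target = "HMGA2"),
    data.frame(source = mirnas[1:7], target = "E2F7"),
    data.frame(source = rep(mirnas[10:11], 3),
               target = rep(c("TFA", "TFB", "TFC"), each = 2)))
  mt$type <- "miRNA-TF"
  tg <- expand.grid(source = tfs, target = genes, stringsAsFactors = FALSE)
  tg$type <- "TF-gene"
  decorate <- function(d, mirna_edge) {
    d$score <- if (mirna_edge) 0.97 else NA_real_
    d$binding_region <- if (mirna_edge) "3'UTR" else NA_character_
    d$p_value <- if (mirna_edge) NA_real_ else 1e-4
    d$species <- "human"
    d
  }
  list(mirna_gene = decorate(mg, TRUE),
       tf_gene = decorate(tg, FALSE),
       mirna_tf = decorate(mt, TRUE))
}
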