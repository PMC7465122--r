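#' Construct a scored undirected interaction graph
#'
#' Canonicalises endpoint order, removes self-loops and duplicate edges
#' (keeping the highest score), auto-detects the 0-1000 STRING score scale
#' (any score above 1 triggers division by 1000), and optionally applies a
#' strict confidence threshold.
#'
#' @param edges data.frame whose first two columns are node identifiers and
#'   which has a `combined_score`/`score` column (or a numeric third column).
#' @param score_threshold edges with score strictly greater are kept; `NULL`
#'   keeps all.
#' @return data.frame with columns `node_a`, `node_b`, `score` (class
#'   `weighted_graph`).
#' @export
weighted_graph <- function(edges, score_threshold = NULL) {
  if (ncol(edges) < 3) stop("edge table needs two node columns and a score column")
  sc_col <- intersect(c("combined_score", "score"), names(edges))
  sc <- if (length(sc_col) > 0) edges[[sc_col[1]]] else edges[[3]]
  sc <- suppressWarnings(as.numeric(sc))
  if (anyNA(sc)) stop("malformed (non-numeric) scores in edge table")
  a <- as.character(edges[[1]])
  b <- as.character(edges[[2]])
  if (max(sc) > 1) sc <- sc / 1000
  g <- data.frame(node_a = pmin(a, b), node_b = pmax(a, b), score = sc,
                  stringsAsFactors = FALSE)
  g <- g[g$node_a != g$node_b, , drop = FALSE]
  if (!is.null(score_threshold)) g <- g[g$score > score_threshold, , drop = FALSE]
  if (nrow(g) == 0) stop("no edges remain after filtering")
  g <- g[order(g$node_a, g$node_b, -g$score), ]
  g <- g[!duplicated(g[, c("node_a", "node_b")]), , drop = FALSE]
  rownames(g) <- NULL
  class(g) <- c("weighted_graph", "data.frame")
  g
}

#' Load a STRING-style edge table from TSV
#'
#' @param path TSV with columns like (protein1, protein2, combined_score).
#' @param score_threshold strict confidence cutoff (default 0.9, the
#'   "highest confidence" STRING setting).
#' @return a `weighted_graph` data.frame.
#' @export
load_string_edges <- function(path, score_threshold = 0.9) {
  weighted_graph(read_edge_table(path), score_threshold = score_threshold)
}

#' MCODE parameters
#'
#' Defaults follow the standard configuration: degree cutoff 2, node score
#' cutoff 0.2, k-core 2, maximum depth 100, haircut on, fluff off.
#'
#' @param degree_cutoff minimum degree for a vertex to be weighted.
#' @param node_score_cutoff admission band below the seed weight, in \[0,1\].
#' @param k_core complexes must contain a k-core of this order.
#' @param max_depth maximum breadth-first expansion depth.
#' @param haircut iteratively remove singly-connected cluster vertices.
#' @return list of class `mcode_params`.
#' @export
mcode_params <- function(degree_cutoff = 2, node_score_cutoff = 0.2,
                         k_core = 2, max_depth = 100, haircut = TRUE) {
  stopifnot(degree_cutoff >= 0, node_score_cutoff >= 0, node_score_cutoff <= 1,
            k_core >= 0, max_depth >= 1)
  structure(list(degree_cutoff = degree_cutoff,
                 node_score_cutoff = node_score_cutoff,
                 k_core = k_core, max_depth = max_depth, haircut = haircut),
            class = "mcode_params")
}

as_igraph_undirected <- function(graph) {
  if (inherits(graph, "igraph")) return(graph)
  igraph::graph_from_data_frame(graph[, c("node_a", "node_b")], directed = FALSE)
}

#' MCODE vertex weights
#'
#' weight(v) = k_max * density of the k_max-core of v's closed neighbourhood
#' (N(v) plus v), where k_max is the highest core order of that
#' neighbourhood subgraph; vertices with degree below the degree cutoff
#' (and isolated vertices) get weight 0.
#'
#' @param graph a `weighted_graph` data.frame or igraph object.
#' @param params an [mcode_params()] list.
#' @return named numeric vector of vertex weights.
#' @export
mcode_vertex_weights <- function(graph, params = mcode_params()) {
  g <- as_igraph_undirected(graph)
  n <- igraph::vcount(g)
  if (n == 0) return(stats::setNames(numeric(0), character(0)))
  nm <- igraph::V(g)$name
  deg <- igraph::degree(g)
  w <- stats::setNames(numeric(n), nm)
  for (i in seq_len(n)) {
    if (deg[i] < params$degree_cutoff) next
    nb <- c(i, as.integer(igraph::neighbors(g, i)))
    sub <- igraph::induced_subgraph(g, unique(nb))
    cores <- igraph::coreness(sub)
    kmax <- max(cores)
    if (kmax == 0) next
    core_sub <- igraph::induced_subgraph(sub, which(cores >= kmax))
    nc <- igraph::vcount(core_sub)
    dens <- if (nc > 1) 2 * igraph::ecount(core_sub) / (nc * (nc - 1)) else 0
    w[i] <- kmax * dens
  }
  w
}

# iterative removal of vertices with < 2 intra-cluster connections (2-core)
haircut_members <- function(g, members) {
  repeat {
    if (length(members) == 0) return(character(0))
    sub <- igraph::induced_subgraph(g, members)
    deg <- igraph::degree(sub)
    low <- names(deg)[deg < 2]
    if (length(low) == 0) break
    members <- setdiff(members, low)
  }
  members
}

#' Detect dense clusters with MCODE
#'
#' Seeds from the unvisited vertex of highest weight and expands
#' breadth-first, admitting neighbours whose weight is at least
#' seed_weight * (1 - node_score_cutoff); vertices never join two clusters.
#' After expansion the haircut removes singly-connected vertices
#' (iteratively, i.e. the cluster's 2-core), clusters must contain a k-core
#' of the configured order, and clusters of fewer than 3 nodes are
#' discarded. Clusters are ranked by score = density * n (descending), ties
#' broken by node count then by lexicographically smallest member.
#'
#' @param graph a `weighted_graph` data.frame or igraph object.
#' @param params an [mcode_params()] list.
#' @return list of clusters, each with `nodes`, `n_nodes`, `n_edges`,
#'   `density`, `score` and `seed`; class `mcode_result`.
#' @export
mcode_find_clusters <- function(graph, params = mcode_params()) {
  g <- as_igraph_undirected(graph)
  w <- mcode_vertex_weights(g, params)
  nm <- names(w)
  ord <- order(-w, nm)
  visited <- stats::setNames(rep(FALSE, length(nm)), nm)
  clusters <- list()
  for (seed in nm[ord]) {
    if (visited[seed] || w[seed] <= 0) next
    thr <- w[seed] * (1 - params$node_score_cutoff)
    members <- seed
    visited[seed] <- TRUE
    frontier <- seed
    depth <- 0
    while (length(frontier) > 0 && depth < params$max_depth) {
      nxt <- character(0)
      for (u in frontier) {
        for (v in igraph::V(g)$name[as.integer(igraph::neighbors(g, u))]) {
          if (!visited[v] && w[v] >= thr) {
            visited[v] <- TRUE
            members <- c(members, v)
            nxt <- c(nxt, v)
          }
        }
      }
      frontier <- nxt
      depth <- depth + 1
    }
    if (params$haircut) members <- haircut_members(g, members)
    if (length(members) < 3) next
    sub <- igraph::induced_subgraph(g, members)
    if (max(igraph::coreness(sub)) < params$k_core) next
    n <- length(members)
    e <- igraph::ecount(sub)
    dens <- 2 * e / (n * (n - 1))
    clusters[[length(clusters) + 1]] <-
      list(nodes = sort(members), n_nodes = n, n_edges = e,
           density = dens, score = dens * n, seed = seed)
  }
  if (length(clusters) > 1) {
    ord2 <- order(-vapply(clusters, `[[`, numeric(1), "score"),
                  -vapply(clusters, `[[`, numeric(1), "n_nodes"),
                  vapply(clusters, function(cl) cl$nodes[1], character(1)))
    clusters <- clusters[ord2]
  }
  structure(clusters, class = "mcode_result")
}

#' MCODE cluster score
#'
#' score = density * n with density = 2E / (n (n - 1)), reported to three
#' decimals. A 24-node, 256-edge cluster scores 22.261.
#'
#' @param n_nodes number of vertices (>= 2).
#' @param n_edges number of edges.
#' @return score rounded to 3 decimals.
#' @export
#' @examples
#' cluster_score(24, 256)
cluster_score <- function(n_nodes, n_edges) {
  if (n_nodes < 2) stop("a cluster needs at least 2 nodes")
  round(2 * n_edges / (n_nodes * (n_nodes - 1)) * n_nodes, 3)
}
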