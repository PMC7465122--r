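# Independent brute-force oracles used to validate the package's
# implementations. These deliberately share no code with the package:
# plain loops, base R only.

# topological overlap by triple loop
oracle_tom <- function(A) {
  n <- nrow(A)
  W <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + A[i, u] * A[u, j]
    ki <- sum(A[i, -i])
    kj <- sum(A[j, -j])
    W[i, j] <- (l + A[i, j]) / (min(ki, kj) + 1 - A[i, j])
  }
  dimnames(W) <- dimnames(A)
  W
}

# BH step-up as "min over the tail of p * m / rank"
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) adj[o[i]] <- min(1, min(p[o][i:m] * m / (i:m)))
  adj
}

# upper-tail hypergeometric by exact enumeration of overlap outcomes
oracle_hyper <- function(overlap, term, universe, query) {
  js <- overlap:min(term, query)
  sum(choose(term, js) * choose(universe - term, query - js)) /
    choose(universe, query)
}

# product-limit estimator over explicit risk sets (deaths before censorings
# at ties)
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ts))
  for (i in seq_along(ts)) {
    n_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  data.frame(time = ts, surv = surv)
}

# --- naive MCODE re-implementation on adjacency lists (no igraph) ---

edges_to_nbrs <- function(edges) {
  nodes <- sort(unique(c(edges$node_a, edges$node_b)))
  nbrs <- stats::setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) {
    nbrs[[v]] <- sort(unique(c(edges$node_b[edges$node_a == v],
                               edges$node_a[edges$node_b == v])))
  }
  nbrs
}

oracle_coreness <- function(nbrs) {
  rem <- names(nbrs)
  core <- stats::setNames(integer(length(nbrs)), names(nbrs))
  k <- 0L
  while (length(rem) > 0) {
    deg <- vapply(rem, function(v) sum(nbrs[[v]] %in% rem), integer(1))
    k <- max(k, min(deg))
    v <- rem[which.min(deg)]
    core[v] <- k
    rem <- setdiff(rem, v)
  }
  core
}

oracle_subgraph <- function(nbrs, keep) {
  out <- lapply(nbrs[keep], function(nb) nb[nb %in% keep])
  names(out) <- keep
  out
}

count_edges <- function(nbrs) sum(lengths(nbrs)) / 2

oracle_mcode_weights <- function(nbrs, degree_cutoff = 2) {
  w <- stats::setNames(numeric(length(nbrs)), names(nbrs))
  for (v in names(nbrs)) {
    if (length(nbrs[[v]]) < degree_cutoff) next
    nh <- oracle_subgraph(nbrs, c(v, nbrs[[v]]))
    core <- oracle_coreness(nh)
    kmax <- max(core)
    if (kmax == 0) next
    ch <- oracle_subgraph(nh, names(core)[core >= kmax])
    nc <- length(ch)
    dens <- if (nc > 1) 2 * count_edges(ch) / (nc * (nc - 1)) else 0
    w[v] <- kmax * dens
  }
  w
}

oracle_mcode <- function(edges, degree_cutoff = 2, node_score_cutoff = 0.2,
                         k_core = 2) {
  nbrs <- edges_to_nbrs(edges)
  w <- oracle_mcode_weights(nbrs, degree_cutoff)
  visited <- stats::setNames(rep(FALSE, length(nbrs)), names(nbrs))
  clusters <- list()
  for (seed in names(w)[order(-w, names(w))]) {
    if (visited[seed] || w[seed] <= 0) next
    thr <- w[seed] * (1 - node_score_cutoff)
    members <- seed
    visited[seed] <- TRUE
    frontier <- seed
    while (length(frontier) > 0) {
      nxt <- character(0)
      for (u in frontier) for (v in nbrs[[u]]) {
        if (!visited[v] && w[v] >= thr) {
          visited[v] <- TRUE
          members <- c(members, v)
          nxt <- c(nxt, v)
        }
      }
      frontier <- nxt
    }
    repeat {  # haircut: iterated removal of singly-connected vertices
      sub <- oracle_subgraph(nbrs, members)
      low <- names(sub)[lengths(sub) < 2]
      if (length(low) == 0) break
      members <- setdiff(members, low)
      if (length(members) == 0) break
    }
    if (length(members) < 3) next
    sub <- oracle_subgraph(nbrs, members)
    if (max(oracle_coreness(sub)) < k_core) next
    n <- length(members)
    e <- count_edges(sub)
    clusters[[length(clusters) + 1]] <-
      list(nodes = sort(members), score = 2 * e / (n * (n - 1)) * n,
           n_nodes = n, n_edges = e)
  }
  if (length(clusters) > 1) {
    ord <- order(-vapply(clusters, `[[`, numeric(1), "score"),
                 -vapply(clusters, `[[`, numeric(1), "n_nodes"),
                 vapply(clusters, function(cl) cl$nodes[1], character(1)))
    clusters <- clusters[ord]
  }
  clusters
}

# triple loop over all node triples, role-checked against the edge list
oracle_motifs <- function(network) {
  e <- network$edges
  nodes <- network$nodes
  found <- list()
  for (m in nodes$node[nodes$role == "miRNA"])
    for (t in nodes$node[nodes$role == "TF"])
      for (g in nodes$node[nodes$role == "gene"]) {
        ok <- any(e$source == m & e$target == t & e$type == "miRNA-TF") &&
          any(e$source == t & e$target == g & e$type == "TF-gene") &&
          any(e$source == m & e$target == g & e$type == "miRNA-gene")
        if (ok) found[[length(found) + 1]] <- c(m, t, g)
      }
  found
}

# adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(sum(tab), 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# random simple undirected graph as a weighted_graph-style edge table
random_graph <- function(n, p, score = 0.95) {
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- t(utils::combn(nodes, 2))
  take <- stats::runif(nrow(pairs)) < p
  if (!any(take)) take[sample(nrow(pairs), 1)] <- TRUE
  data.frame(node_a = pairs[take, 1], node_b = pairs[take, 2], score = score)
}
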