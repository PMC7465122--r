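#' Absolute-Pearson similarity matrix
#'
#' s_ij = |cor(x_i, x_j)| over samples; unsigned co-expression similarity.
#'
#' @param gene_matrix genes x samples matrix with >= 3 samples.
#' @return symmetric matrix with entries in \[0, 1\], unit diagonal.
#' @export
similarity_matrix <- function(gene_matrix) {
  if (ncol(gene_matrix) < 3) stop("at least 3 samples are required")
  v <- apply(gene_matrix, 1, stats::var)
  if (any(v <= 0)) stop("zero-variance gene(s): ",
                        paste(utils::head(rownames(gene_matrix)[v <= 0]), collapse = ", "))
  S <- abs(stats::cor(t(gene_matrix)))
  S[S > 1] <- 1
  diag(S) <- 1
  S
}

#' Soft-thresholded adjacency
#'
#' a_ij = s_ij^beta with a zero diagonal (self-adjacency is excluded from
#' all connectivity sums).
#'
#' @param S similarity matrix.
#' @param beta positive soft-thresholding power.
#' @return adjacency matrix.
#' @export
adjacency_matrix <- function(S, beta) {
  stopifnot(beta >= 1)
  A <- S^beta
  diag(A) <- 0
  A
}

# scale-free fit: equal-count (quantile) bins of the connectivity vector,
# empirical density per bin, regression of log10(density) on log10(mean k).
# signed R^2 = -sign(slope) * R^2 so only decaying distributions score high.
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  br <- unique(stats::quantile(k, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 4) return(list(signed_r2 = NA_real_, slope = NA_real_))
  bins <- cut(k, breaks = br, include.lowest = TRUE)
  cnt <- tabulate(bins, nbins = nlevels(bins))
  width <- diff(br)
  dens <- cnt / (sum(cnt) * width)
  mk <- tapply(k, bins, mean)
  keep <- cnt > 0 & dens > 0
  if (sum(keep) < 3) return(list(signed_r2 = NA_real_, slope = NA_real_))
  fit <- stats::lm(log10(dens[keep]) ~ log10(mk[keep]))
  sl <- unname(stats::coef(fit)[2])
  list(signed_r2 = -sign(sl) * summary(fit)$r.squared, slope = sl)
}

#' Pick the soft-thresholding power by the scale-free topology criterion
#'
#' For each candidate power the whole-network connectivities k_i are binned
#' into equal-count bins and log10(density) is regressed on log10(mean k);
#' the signed fit index is -sign(slope) * R^2. The smallest power reaching
#' `target_r2` is chosen; if none reaches it, the argmax is returned with a
#' warning and `reached_target = FALSE`.
#'
#' @param S similarity matrix (>= 30 genes for a meaningful fit).
#' @param powers candidate integer powers (default 1:20).
#' @param target_r2 target signed R^2 (default 0.80).
#' @param n_bins number of connectivity bins (default 10).
#' @return list with `beta`, `fits` (data.frame power/signed_r2/slope) and
#'   `reached_target`.
#' @export
pick_soft_threshold <- function(S, powers = 1:20, target_r2 = 0.80, n_bins = 10) {
  if (nrow(S) < 30) stop("at least 30 genes are required for a degree-distribution fit")
  fits <- lapply(powers, function(b) {
    k <- rowSums(adjacency_matrix(S, b))
    if (stats::sd(k) == 0) stop("degenerate connectivities: all genes equally connected")
    scale_free_fit(k, n_bins)
  })
  df <- data.frame(power = powers,
                   signed_r2 = vapply(fits, `[[`, numeric(1), "signed_r2"),
                   slope = vapply(fits, `[[`, numeric(1), "slope"))
  hit <- which(!is.na(df$signed_r2) & df$signed_r2 >= target_r2)
  if (length(hit) > 0) {
    beta <- powers[hit[1]]
    reached <- TRUE
  } else {
    beta <- powers[which.max(df$signed_r2)]
    reached <- FALSE
    warning("no candidate power reached signed R^2 >= ", target_r2,
            "; using argmax power ", beta)
  }
  list(beta = beta, fits = df, reached_target = reached)
}

#' Topological overlap matrix (unsigned)
#'
#' omega_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij) with
#' l_ij = sum_u a_iu a_uj; the default unsigned TOM used with weighted
#' co-expression networks. Diagonal is 1.
#'
#' @param A symmetric adjacency matrix with entries in \[0, 1\] and zero
#'   diagonal.
#' @return TOM matrix with entries in \[0, 1\].
#' @export
tom_matrix <- function(A) {
  if (any(A < 0)) stop("adjacency entries must be non-negative")
  if (any(A > 1)) stop("adjacency entries must not exceed 1")
  if (!isSymmetric(unname(A), tol = 1e-10)) stop("adjacency must be symmetric")
  diag(A) <- 0
  L <- A %*% A
  k <- rowSums(A)
  kmin <- outer(k, k, pmin)
  W <- (L + A) / (kmin + 1 - A)
  diag(W) <- 1
  W[W > 1] <- 1
  W[W < 0] <- 0
  W
}

#' Detect modules by adaptive dendrogram cutting
#'
#' Builds an average-linkage dendrogram of the TOM dissimilarity and cuts it
#' at the height that maximises the number of branches of at least
#' `min_module_size` genes (the largest such height is used, so branches are
#' as complete as possible). Branches smaller than `min_module_size` are
#' assigned to "grey"; module colours are given in decreasing size order
#' from a fixed palette.
#'
#' @param dissTOM dissimilarity matrix (1 - TOM) with gene dimnames.
#' @param min_module_size smallest cluster kept as a module (default 30).
#' @return list with `labels` (named character vector, "grey" = unassigned),
#'   `dendrogram` (the hclust object) and `cut_height`.
#' @export
cluster_and_cut <- function(dissTOM, min_module_size = 30) {
  genes <- rownames(dissTOM)
  n <- nrow(dissTOM)
  if (n < min_module_size) {
    warning("fewer genes than min_module_size; all genes assigned to grey")
    return(list(labels = stats::setNames(rep("grey", n), genes),
                dendrogram = NULL, cut_height = NA_real_))
  }
  hc <- stats::hclust(stats::as.dist(dissTOM), method = "average")
  # average linkage is monotone; guard against floating-point inversions at
  # tied merge heights, which cutree(h = ...) rejects
  hc$height <- cummax(hc$height)
  hs <- sort(unique(hc$height))
  cuts <- if (length(hs) > 1) (hs[-1] + hs[-length(hs)]) / 2 else numeric(0)
  cuts <- c(hs[1] / 2, cuts, hs[length(hs)] + abs(hs[length(hs)]) + 1)
  best_cut <- cuts[length(cuts)]
  best_n <- -1L
  for (h in cuts) {
    cl <- stats::cutree(hc, h = h)
    nn <- sum(table(cl) >= min_module_size)
    if (nn >= best_n) {  # >= : prefer the largest height achieving the max
      best_n <- nn
      best_cut <- h
    }
  }
  cl <- stats::cutree(hc, h = best_cut)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  keep <- keep[order(-sizes[keep], as.integer(keep))]
  labels <- rep("grey", n)
  cols <- module_colors(length(keep))
  for (i in seq_along(keep)) labels[cl == as.integer(keep[i])] <- cols[i]
  list(labels = stats::setNames(labels, genes), dendrogram = hc,
       cut_height = best_cut)
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' row-standardised expression submatrix, scaled to unit variance and
#' sign-oriented so that it correlates positively with the module's average
#' standardised expression.
#'
#' @param gene_matrix genes x samples matrix.
#' @param labels named module labels ("grey" = unassigned).
#' @return matrix, samples x modules, one unit-variance eigengene per
#'   non-grey module.
#' @export
module_eigengenes <- function(gene_matrix, labels) {
  mods <- setdiff(sort(unique(labels)), "grey")
  if (length(mods) == 0) stop("no non-grey modules")
  ME <- sapply(mods, function(m) {
    g <- names(labels)[labels == m]
    if (length(g) < 2) stop("module '", m, "' has a single gene; no eigengene defined")
    sub <- gene_matrix[g, , drop = FALSE]
    z <- t(scale(t(sub)))
    if (anyNA(z)) stop("zero-variance gene inside module '", m, "'")
    sv <- svd(z, nu = 0, nv = 1)
    me <- sv$v[, 1]
    me <- me / stats::sd(me)
    if (stats::cor(me, colMeans(z)) < 0) me <- -me
    me
  })
  rownames(ME) <- colnames(gene_matrix)
  ME
}

#' Merge modules with similar eigengenes
#'
#' Iteratively merges the pair of modules with the smallest eigengene
#' dissimilarity (1 - cor(ME_i, ME_j)) while it is below `merge_height`
#' (default 0.2, i.e. eigengene correlation above 0.8), recomputing
#' eigengenes after each merge. The label of the larger module survives.
#'
#' @param gene_matrix genes x samples matrix.
#' @param labels named module labels.
#' @param merge_height MEdiss threshold below which modules merge.
#' @return list with updated `labels` and the final `eigengenes` matrix.
#' @export
merge_close_modules <- function(gene_matrix, labels, merge_height = 0.2) {
  repeat {
    mods <- setdiff(unique(labels), "grey")
    if (length(mods) < 2) break
    ME <- module_eigengenes(gene_matrix, labels)
    D <- 1 - stats::cor(ME)
    diag(D) <- Inf
    ij <- which(D == min(D), arr.ind = TRUE)[1, ]
    if (D[ij[1], ij[2]] >= merge_height) break
    a <- colnames(ME)[ij[1]]
    b <- colnames(ME)[ij[2]]
    na <- sum(labels == a)
    nb <- sum(labels == b)
    winner <- if (na > nb) a else if (nb > na) b else min(a, b)
    loser <- if (winner == a) b else a
    labels[labels == loser] <- winner
  }
  list(labels = labels, eigengenes = module_eigengenes(gene_matrix, labels))
}

#' Connectivity and module-membership statistics
#'
#' Computes, per gene: whole-network connectivity kTotal = sum_j a_ij,
#' intramodular connectivity k.in (adjacency summed over same-module
#' partners), its TOM analogue omega.in, kOut = kTotal - k.in,
#' kDiff = k.in - kOut, the kME profile (correlation of the gene's
#' expression with each module eigengene) and MM, the kME of the gene's own
#' module. Genes whose best |kME| falls below `kme_floor` are reassigned to
#' grey (applied once).
#'
#' @param A adjacency matrix (zero diagonal).
#' @param TOM topological overlap matrix.
#' @param gene_matrix genes x samples matrix.
#' @param labels named module labels.
#' @param kme_floor minimum |kME| needed to stay in a module (default 0.7).
#' @return data.frame (gene, module, MM, k.in, omega.in, kTotal, kOut,
#'   kDiff) with the full kME matrix attached as attribute `kME`.
#' @export
connectivity_table <- function(A, TOM, gene_matrix, labels, kme_floor = 0.7) {
  genes <- names(labels)
  ME <- module_eigengenes(gene_matrix, labels)
  kME <- stats::cor(t(gene_matrix[genes, , drop = FALSE]), ME)
  rownames(kME) <- genes
  best <- apply(abs(kME), 1, max)
  reassigned <- labels != "grey" & best < kme_floor
  if (any(reassigned)) {
    message(sum(reassigned), " gene(s) with max |kME| < ", kme_floor,
            " reassigned to grey")
    labels[reassigned] <- "grey"
  }
  W <- TOM
  diag(W) <- 0
  kTotal <- rowSums(A)[genes]
  k_in <- omega_in <- rep(NA_real_, length(genes))
  MM <- rep(NA_real_, length(genes))
  for (m in setdiff(unique(labels), "grey")) {
    idx <- which(labels == m)
    members <- genes[idx]
    k_in[idx] <- rowSums(A[members, members, drop = FALSE])
    omega_in[idx] <- rowSums(W[members, members, drop = FALSE])
    if (m %in% colnames(kME)) MM[idx] <- kME[members, m]
  }
  out <- data.frame(gene = genes, module = unname(labels), MM = MM,
                    k.in = k_in, omega.in = omega_in, kTotal = kTotal,
                    kOut = kTotal - k_in, kDiff = 2 * k_in - kTotal,
                    row.names = NULL)
  attr(out, "kME") <- kME
  out
}

#' Representative genes per module
#'
#' Genes with module membership strictly above `mm_threshold`; the grey
#' (unassigned) pseudo-module is excluded.
#'
#' @param table connectivity table from [connectivity_table()].
#' @param mm_threshold MM cutoff (default 0.9, strict).
#' @return named list of character vectors, one per module.
#' @export
representative_genes <- function(table, mm_threshold = 0.9) {
  sel <- table$module != "grey" & !is.na(table$MM) & table$MM > mm_threshold
  split(table$gene[sel], table$module[sel])
}

#' Full weighted co-expression analysis
#'
#' Similarity, soft-threshold selection, adjacency, TOM, module detection,
#' eigengene-based merging, connectivity statistics (with the |kME| floor
#' reassignment) and representative-gene screening, in one call.
#'
#' @param gene_matrix genes x samples log2 expression matrix.
#' @param powers candidate soft-thresholding powers.
#' @param target_r2 scale-free fit target (default 0.80).
#' @param min_module_size smallest module size (default 30).
#' @param merge_height eigengene-dissimilarity merge threshold (default 0.2).
#' @param kme_floor minimum |kME| (default 0.7).
#' @param mm_threshold representative-gene MM cutoff (default 0.9).
#' @return list with `beta`, `fits`, `partition` (pre-merge), `labels`
#'   (final), `eigengenes`, `connectivity`, `representative`, and the
#'   `similarity`/`adjacency`/`tom` matrices.
#' @export
run_gcn <- function(gene_matrix, powers = 1:20, target_r2 = 0.80,
                    min_module_size = 30, merge_height = 0.2,
                    kme_floor = 0.7, mm_threshold = 0.9) {
  S <- similarity_matrix(gene_matrix)
  st <- pick_soft_threshold(S, powers = powers, target_r2 = target_r2)
  A <- adjacency_matrix(S, st$beta)
  TOM <- tom_matrix(A)
  part <- cluster_and_cut(1 - TOM, min_module_size = min_module_size)
  labels <- part$labels
  if (all(labels == "grey")) {
    warning("no modules detected; downstream module statistics unavailable")
    return(list(beta = st$beta, fits = st$fits, partition = part,
                labels = labels, eigengenes = NULL, connectivity = NULL,
                representative = list(), similarity = S, adjacency = A,
                tom = TOM))
  }
  merged <- merge_close_modules(gene_matrix, labels, merge_height = merge_height)
  ct <- connectivity_table(A, TOM, gene_matrix, merged$labels,
                           kme_floor = kme_floor)
  final_labels <- stats::setNames(ct$module, ct$gene)
  list(beta = st$beta, fits = st$fits, reached_target = st$reached_target,
       partition = part, labels = final_labels,
       eigengenes = merged$eigengenes, connectivity = ct,
       representative = representative_genes(ct, mm_threshold = mm_threshold),
       similarity = S, adjacency = A, tom = TOM)
}
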