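#' Collapse probe-level rows to gene symbols
#'
#' Probes mapping to the same gene symbol are averaged (arithmetic mean per
#' sample); probes without a symbol are dropped. Output rows are ordered
#' lexicographically by symbol.
#'
#' @param probe_matrix numeric matrix, probes in rows, samples in columns.
#' @param annotation either a data.frame with columns `probe_id` and
#'   `symbol`, or a named character vector (names = probe IDs, values =
#'   symbols). Empty or `NA` symbols mark unmapped probes.
#' @return numeric matrix with one row per unique symbol.
#' @export
collapse_probes <- function(probe_matrix, annotation) {
  if (is.data.frame(annotation)) {
    stopifnot(all(c("probe_id", "symbol") %in% names(annotation)))
    map <- stats::setNames(as.character(annotation$symbol),
                           as.character(annotation$probe_id))
  } else {
    map <- annotation
  }
  sym <- map[rownames(probe_matrix)]
  keep <- !is.na(sym) & nzchar(sym)
  if (!any(keep)) stop("no probes map to a gene symbol")
  m <- probe_matrix[keep, , drop = FALSE]
  g <- sym[keep]
  sums <- rowsum(m, group = g)
  counts <- as.vector(table(g)[rownames(sums)])
  out <- sums / counts
  out[order(rownames(out)), , drop = FALSE]
}

#' Align expression matrices on their common genes
#'
#' @param matrices list of two or more gene-by-sample matrices with gene
#'   rownames.
#' @return list of matrices, all with the identical sorted gene index equal
#'   to the set intersection of the input gene sets.
#' @export
intersect_genes <- function(matrices) {
  stopifnot(is.list(matrices), length(matrices) >= 2)
  common <- Reduce(intersect, lapply(matrices, rownames))
  if (length(common) == 0) stop("no genes are common to all datasets")
  common <- sort(common)
  lapply(matrices, function(m) m[common, , drop = FALSE])
}

# order tumor/normal columns by subject; errors unless every subject has
# exactly one of each
paired_columns <- function(gene_matrix, samples) {
  stopifnot(all(c("sample_id", "subject_id", "condition") %in% names(samples)))
  if (!all(samples$condition %in% c("tumor", "normal")))
    stop("condition must be 'tumor' or 'normal'")
  if (anyDuplicated(samples$sample_id)) stop("sample IDs must be unique")
  missing_cols <- setdiff(samples$sample_id, colnames(gene_matrix))
  if (length(missing_cols) > 0)
    stop("samples absent from the matrix: ", paste(missing_cols, collapse = ", "))
  tab <- table(samples$subject_id, samples$condition)
  if (!all(tab == 1))
    stop("every subject must contribute exactly one tumor and one normal sample")
  subjects <- sort(unique(samples$subject_id))
  pick <- function(cond) {
    sel <- samples[samples$condition == cond, ]
    sel$sample_id[match(subjects, sel$subject_id)]
  }
  list(subjects = subjects, tumor = pick("tumor"), normal = pick("normal"))
}

#' Per-gene paired t-test
#'
#' Classic paired t on the per-subject tumor-minus-normal differences:
#' t = mean(d) / (sd(d)/sqrt(n)), df = n - 1, two-sided p from the Student
#' t distribution. Genes with zero difference variance get `NA` p-values
#' (reported, not silently set to 0).
#'
#' @param gene_matrix genes x samples log2 expression matrix.
#' @param samples sample sheet (`sample_id`, `subject_id`, `condition`).
#' @return data.frame with columns `gene`, `mean_diff`, `t`, `df`, `p`.
#' @export
paired_t_test <- function(gene_matrix, samples) {
  pc <- paired_columns(gene_matrix, samples)
  n <- length(pc$subjects)
  if (n < 2) stop("at least 2 subject pairs are required")
  d <- gene_matrix[, pc$tumor, drop = FALSE] - gene_matrix[, pc$normal, drop = FALSE]
  m <- rowMeans(d)
  s <- sqrt(rowSums((d - m)^2) / (n - 1))
  zero <- s <= 0
  tstat <- ifelse(zero, NA_real_, m / (s / sqrt(n)))
  p <- 2 * stats::pt(abs(tstat), df = n - 1, lower.tail = FALSE)
  if (any(zero))
    message(sum(zero), " gene(s) with zero-variance differences; p set to NA")
  data.frame(gene = rownames(gene_matrix), mean_diff = m, t = tstat,
             df = n - 1, p = p, row.names = NULL)
}

#' Fisher's combined probability test
#'
#' Combines per-dataset p-values per gene: X = -2 * sum(ln p_i), with the
#' combined p the upper tail of a chi-squared distribution with 2k degrees
#' of freedom. Zero p-values are clamped to the smallest positive double so
#' the statistic stays finite. Rows containing `NA` propagate `NA`.
#'
#' @param p_values numeric matrix (genes x datasets) or vector (one dataset).
#' @return data.frame with columns `X` and `p_combined`.
#' @export
fisher_combine <- function(p_values) {
  p <- as.matrix(p_values)
  k <- ncol(p)
  if (k < 1) stop("at least one dataset of p-values is required")
  finite <- !is.na(p)
  if (any(p[finite] < 0 | p[finite] > 1)) stop("p-values must lie in [0, 1]")
  p[finite & p == 0] <- .Machine$double.xmin
  X <- -2 * rowSums(log(p))
  data.frame(X = X,
             p_combined = stats::pchisq(X, df = 2 * k, lower.tail = FALSE),
             row.names = rownames(p))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Input order is preserved; `NA` entries (e.g. zero-variance genes) are
#' excluded from the adjustment so they do not inflate the number of tests.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Per-gene log2 fold change, pooled across datasets
#'
#' log2FC = mean over all tumor samples (pooled across datasets) minus mean
#' over all normal samples. Per-dataset fold changes are also returned for
#' audit.
#'
#' @param matrices list of aligned gene x sample matrices (log2 scale).
#' @param samples_list list of matching sample sheets.
#' @return data.frame with `gene`, `log2fc`, and one `log2fc_ds<i>` column
#'   per dataset.
#' @export
compute_log2fc <- function(matrices, samples_list) {
  stopifnot(length(matrices) == length(samples_list))
  per <- lapply(seq_along(matrices), function(i) {
    pc <- paired_columns(matrices[[i]], samples_list[[i]])
    list(tumor = matrices[[i]][, pc$tumor, drop = FALSE],
         normal = matrices[[i]][, pc$normal, drop = FALSE])
  })
  tum <- do.call(cbind, lapply(per, `[[`, "tumor"))
  nor <- do.call(cbind, lapply(per, `[[`, "normal"))
  out <- data.frame(gene = rownames(matrices[[1]]),
                    log2fc = rowMeans(tum) - rowMeans(nor), row.names = NULL)
  for (i in seq_along(per)) {
    out[[paste0("log2fc_ds", i)]] <-
      rowMeans(per[[i]]$tumor) - rowMeans(per[[i]]$normal)
  }
  out
}

#' Classify meta-differentially-expressed genes
#'
#' Strict thresholds: `up` requires adjusted p < `alpha` and
#' log2FC > `fc_threshold`; `down` requires adjusted p < `alpha` and
#' log2FC < -`fc_threshold`; everything else (including exact boundary
#' values) is `not_significant`.
#'
#' @param table data.frame with at least `p_bh` and `log2fc` columns.
#' @param alpha adjusted-p cutoff (default 1e-4).
#' @param fc_threshold absolute log2 fold-change cutoff (default 1.5).
#' @return the table with a `class` column added.
#' @export
call_meta_degs <- function(table, alpha = 1e-4, fc_threshold = 1.5) {
  stopifnot(all(c("p_bh", "log2fc") %in% names(table)))
  sig <- !is.na(table$p_bh) & table$p_bh < alpha
  cls <- rep("not_significant", nrow(table))
  cls[sig & table$log2fc > fc_threshold] <- "up"
  cls[sig & table$log2fc < -fc_threshold] <- "down"
  table$class <- cls
  table
}

# matrices on an intensity scale are log2(x+1)-transformed; a heuristic on
# the maximum value (series-matrix log2 data rarely exceeds 30)
maybe_log2 <- function(mat) {
  if (max(mat, na.rm = TRUE) > 30) {
    warning("matrix maximum exceeds 30; assuming unlogged input and applying log2(x + 1)")
    mat <- log2(mat + 1)
  }
  mat
}

#' Meta-differential-expression across paired datasets
#'
#' Runs the full meta-analysis: optional probe collapsing, gene
#' intersection, per-dataset paired t-tests, Fisher's combined probability,
#' Benjamini-Hochberg correction and pooled log2 fold change, then
#' classifies genes as up/down/not significant at the given thresholds.
#'
#' @param exprs list of >= 2 gene-by-sample log2 expression matrices.
#' @param samples list of matching sample sheets.
#' @param annotation optional list of probe-to-symbol annotations (one per
#'   dataset); `NULL` entries mean the matrix is already gene-level.
#' @param alpha BH-adjusted p cutoff (default 1e-4).
#' @param fc_threshold absolute log2FC cutoff (default 1.5).
#' @return list with `table` (the per-gene meta-DEG table), `n_up`,
#'   `n_down`, and `aligned` (the intersected matrices).
#' @export
run_meta_deg <- function(exprs, samples, annotation = NULL,
                         alpha = 1e-4, fc_threshold = 1.5) {
  stopifnot(length(exprs) >= 2, length(exprs) == length(samples))
  exprs <- lapply(seq_along(exprs), function(i) {
    m <- exprs[[i]]
    if (!is.null(annotation) && !is.null(annotation[[i]]))
      m <- collapse_probes(m, annotation[[i]])
    maybe_log2(m)
  })
  aligned <- intersect_genes(exprs)
  tests <- lapply(seq_along(aligned), function(i)
    paired_t_test(aligned[[i]], samples[[i]]))
  pmat <- do.call(cbind, lapply(tests, `[[`, "p"))
  colnames(pmat) <- paste0("p_ds", seq_along(tests))
  fc <- fisher_combine(pmat)
  tab <- data.frame(gene = rownames(aligned[[1]]), pmat, X = fc$X,
                    p_combined = fc$p_combined,
                    p_bh = bh_adjust(fc$p_combined), row.names = NULL)
  lfc <- compute_log2fc(aligned, samples)
  tab <- cbind(tab, lfc[, -1, drop = FALSE])
  tab <- call_meta_degs(tab, alpha = alpha, fc_threshold = fc_threshold)
  list(table = tab,
       n_up = sum(tab$class == "up"),
       n_down = sum(tab$class == "down"),
       aligned = aligned)
}
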