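#' Pipeline configuration
#'
#' Collects all input paths and analysis thresholds. Every default
#' threshold is the published one, so a bare run reproduces the reference
#' analysis settings: meta-DEG BH alpha 1e-4 with |log2FC| > 1.5,
#' scale-free R^2 target 0.80, eigengene merge height 0.2, MM > 0.9,
#' |kME| >= 0.7, interaction confidence > 0.9, enrichment BH alpha 0.001,
#' miRNA target score > 0.95, TF p < 0.001.
#'
#' @param paths named list of input file paths: `expr` and `samples`
#'   (character vectors, one per dataset), `ppi`, `gmt` (one or more GMT
#'   files), `mirna_gene`, `tf_gene`, `mirna_tf`, `mouse_mirna_gene`,
#'   `mouse_mirna_tf`, `tier1`, `survival`.
#' @param alpha_meta,fc meta-DEG thresholds.
#' @param r2_target,min_module_size,merge_height,mm_threshold,kme_floor
#'   co-expression parameters.
#' @param string_threshold interaction confidence cutoff (strict).
#' @param enrich_alpha enrichment BH threshold (strict).
#' @param mirna_score,tf_p regulatory filter thresholds.
#' @param conserve_targets mouse-conservation scope, `"all"` or `"genes"`.
#' @param seed integer seed recorded for provenance.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(paths,
                            alpha_meta = 1e-4, fc = 1.5,
                            r2_target = 0.80, min_module_size = 30,
                            merge_height = 0.2, mm_threshold = 0.9,
                            kme_floor = 0.7,
                            string_threshold = 0.9,
                            enrich_alpha = 0.001,
                            mirna_score = 0.95, tf_p = 0.001,
                            conserve_targets = "all",
                            seed = 1) {
  stopifnot(alpha_meta > 0, alpha_meta < 1, fc >= 0,
            r2_target > 0, r2_target <= 1,
            merge_height >= 0, merge_height <= 2,
            mm_threshold >= 0, mm_threshold <= 1,
            kme_floor >= 0, kme_floor <= 1,
            string_threshold >= 0, string_threshold <= 1,
            enrich_alpha > 0, enrich_alpha < 1,
            mirna_score >= 0, mirna_score <= 1, tf_p > 0, tf_p < 1)
  structure(list(paths = paths, alpha_meta = alpha_meta, fc = fc,
                 r2_target = r2_target, min_module_size = min_module_size,
                 merge_height = merge_height, mm_threshold = mm_threshold,
                 kme_floor = kme_floor, string_threshold = string_threshold,
                 enrich_alpha = enrich_alpha, mirna_score = mirna_score,
                 tf_p = tf_p, conserve_targets = conserve_targets,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Standard input paths of a simulated bundle directory
#'
#' @param dir a directory written by [simulate_bundle()].
#' @param n_datasets number of expression datasets in the bundle.
#' @return named list of paths suitable for [pipeline_config()].
#' @export
bundle_paths <- function(dir, n_datasets = 2) {
  list(expr = file.path(dir, sprintf("expr_ds%d.tsv", seq_len(n_datasets))),
       samples = file.path(dir, sprintf("samples_ds%d.tsv", seq_len(n_datasets))),
       ppi = file.path(dir, "ppi_edges.tsv"),
       gmt = file.path(dir, c("genesets_go_bp.gmt", "genesets_pathway.gmt")),
       mirna_gene = file.path(dir, "mirna_gene.tsv"),
       tf_gene = file.path(dir, "tf_gene.tsv"),
       mirna_tf = file.path(dir, "mirna_tf.tsv"),
       mouse_mirna_gene = file.path(dir, "mouse_mirna_gene.tsv"),
       mouse_mirna_tf = file.path(dir, "mouse_mirna_tf.tsv"),
       tier1 = file.path(dir, "tier1.txt"),
       survival = file.path(dir, "survival.tsv"))
}

#' Merge aligned datasets for co-expression analysis
#'
#' Column-binds the aligned matrices; by default each gene is centred per
#' dataset first, removing dataset-specific baselines so that pooled
#' correlations reflect biology rather than batch.
#'
#' @param matrices list of aligned gene x sample matrices.
#' @param center centre each gene within each dataset (default TRUE).
#' @return one merged gene x sample matrix.
#' @export
merge_datasets <- function(matrices, center = TRUE) {
  if (center) matrices <- lapply(matrices, function(m) m - rowMeans(m))
  do.call(cbind, matrices)
}

stage_run <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order -- meta-differential expression, weighted
#' co-expression modules, dense-cluster detection on the interaction
#' network (restricted to representative module genes), enrichment-based
#' hub calling, feed-forward-loop assembly (regulatory edges restricted to
#' hub-gene targets), and median-split survival per hub gene -- writing
#' each stage's table plus a machine-readable `summary.json` into
#' `out_dir`. All inputs are validated before any computation; any stage
#' error aborts with the stage name.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory for stage tables and the summary.
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  p <- config$paths
  all_files <- unlist(p)
  missing <- all_files[!file.exists(all_files)]
  if (length(missing) > 0)
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(parameters = unclass(config)[setdiff(names(config), "paths")])

  # 1. meta-differential expression
  meta <- stage_run("meta_deg", {
    exprs <- lapply(p$expr, read_expression_tsv)
    samples <- lapply(p$samples, read_sample_sheet)
    run_meta_deg(exprs, samples, alpha = config$alpha_meta,
                 fc_threshold = config$fc)
  })
  write_tsv(meta$table, file.path(out_dir, "meta_degs.tsv"))
  summary$meta_deg <- list(n_genes_tested = nrow(meta$table),
                           n_meta_degs = meta$n_up + meta$n_down,
                           n_up = meta$n_up, n_down = meta$n_down)

  # 2. weighted co-expression modules on the meta-DEGs
  gcn <- stage_run("gcn", {
    degs <- meta$table$gene[meta$table$class != "not_significant"]
    if (length(degs) < 3) stop("fewer than 3 meta-DEGs; cannot build a network")
    merged <- merge_datasets(lapply(meta$aligned, function(m)
      m[degs, , drop = FALSE]))
    run_gcn(merged, target_r2 = config$r2_target,
            min_module_size = config$min_module_size,
            merge_height = config$merge_height,
            kme_floor = config$kme_floor,
            mm_threshold = config$mm_threshold)
  })
  write_tsv(gcn$connectivity, file.path(out_dir, "modules.tsv"))
  rep_genes <- sort(unique(unlist(gcn$representative)))
  msz <- table(gcn$labels[gcn$labels != "grey"])
  summary$gcn <- list(beta = gcn$beta,
                      reached_r2_target = isTRUE(gcn$reached_target),
                      n_modules = length(msz),
                      module_sizes = as.list(msz),
                      n_grey = sum(gcn$labels == "grey"),
                      n_representative = length(rep_genes))

  # 3. dense clusters in the interaction network of representative genes
  ppi <- stage_run("ppi_cluster", {
    g <- load_string_edges(p$ppi, score_threshold = config$string_threshold)
    g <- g[g$node_a %in% rep_genes & g$node_b %in% rep_genes, , drop = FALSE]
    if (nrow(g) == 0) stop("no interactions among representative genes")
    clusters <- mcode_find_clusters(g)
    if (length(clusters) == 0) stop("no dense cluster found")
    list(graph = g, clusters = clusters)
  })
  top <- ppi$clusters[[1]]
  writeLines(top$nodes, file.path(out_dir, "top_cluster_genes.txt"))
  summary$ppi_cluster <- list(
    n_nodes = length(unique(c(ppi$graph$node_a, ppi$graph$node_b))),
    n_edges = nrow(ppi$graph),
    n_clusters = length(ppi$clusters),
    top_cluster = list(nodes = top$nodes, n_nodes = top$n_nodes,
                       n_edges = top$n_edges,
                       score = cluster_score(top$n_nodes, top$n_edges)))

  # 4. enrichment of the top cluster and hub calling
  enr <- stage_run("enrichment_hub", {
    libs <- lapply(p$gmt, read_gmt)
    results <- lapply(libs, function(l)
      enrich(top$nodes, l, alpha = config$enrich_alpha))
    list(results = results,
         hubs = hub_genes(results, alpha = config$enrich_alpha))
  })
  for (i in seq_along(enr$results))
    write_tsv(enr$results[[i]],
              file.path(out_dir, sprintf("enrichment_%d.tsv", i)))
  writeLines(enr$hubs, file.path(out_dir, "hub_genes.txt"))
  summary$enrichment_hub <- list(
    n_significant_terms = sum(vapply(enr$results, function(r)
      sum(r$significant), integer(1))),
    hub_genes = enr$hubs)

  # 5. feed-forward-loop network restricted to hub-gene targets
  ffl <- stage_run("ffl", {
    human <- rbind(read_edge_table(p$mirna_gene), read_edge_table(p$tf_gene),
                   read_edge_table(p$mirna_tf))
    gene_edge <- human$type %in% c("miRNA-gene", "TF-gene")
    human <- human[!gene_edge | human$target %in% enr$hubs, , drop = FALSE]
    mouse <- list(read_edge_table(p$mouse_mirna_gene),
                  read_edge_table(p$mouse_mirna_tf))
    tier1 <- read_screen_list(p$tier1)
    screened <- two_tier_screen(
      filter_regulatory_edges(human, mirna_score = config$mirna_score,
                              tf_p = config$tf_p),
      tier1, mouse, conserve_targets = config$conserve_targets,
      mirna_score = config$mirna_score, tf_p = config$tf_p)
    net <- assemble_ffl_network(screened)
    list(network = net, motif = if (net$n_edges > 0)
      suppressMessages(highest_order_motif(net)) else NULL)
  })
  write_sif(ffl$network, file.path(out_dir, "ffl_network.sif"))
  summary$ffl <- list(
    n_nodes = ffl$network$n_nodes, n_edges = ffl$network$n_edges,
    edge_counts = as.list(ffl$network$edge_counts),
    motif = if (is.null(ffl$motif)) NULL else
      list(mirna = ffl$motif$mirna, tfs = ffl$motif$tfs,
           gene = ffl$motif$gene, order = ffl$motif$order))

  # 6. median-split survival per hub gene
  surv <- stage_run("survival", {
    tab <- read_survival_table(p$survival)
    genes <- intersect(enr$hubs, names(tab))
    lapply(stats::setNames(genes, genes), function(g) km_analysis(tab, g))
  })
  summary$survival <- lapply(surv, function(r)
    list(hr = r$hr$hr, ci_low = r$hr$ci_low, ci_high = r$hr$ci_high,
         logrank_p = r$logrank$p,
         median_low = r$cohorts$low$median,
         median_high = r$cohorts$high$median))

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(summary)
}
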