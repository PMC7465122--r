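#' Simulation configuration with planted ground truth
#'
#' Defines the study conditions for the synthetic fixture: two (or more)
#' paired tumour/normal cohorts sharing planted up/down-regulated genes,
#' latent-factor co-expression modules, a near-clique of hub genes in the
#' interaction network, a planted composite feed-forward loop and
#' expression-dependent survival.
#'
#' Module genes are generated as loading * latent factor + Gaussian noise;
#' a small set of "core" genes per module carries a higher loading
#' (`core_loading`, with noise variance 1 - core_loading^2) so that their
#' correlation with the module eigengene is approximately `core_loading` --
#' these are the genes a module-membership screen should recover, and the
#' planted interaction clique is drawn from the first module's cores.
#'
#' @param n_genes number of genes in the simulated universe.
#' @param n_pairs_per_dataset integer vector: tumour/normal pairs per
#'   dataset (one entry per dataset).
#' @param de_fraction fraction of genes differentially expressed.
#' @param de_effect tumour-minus-normal mean shift of DE genes (log2 units).
#' @param n_modules number of planted co-expression modules (0 allowed).
#' @param module_sizes integer vector of module sizes.
#' @param factor_loading latent-factor loading of regular module genes.
#' @param noise_sd per-gene Gaussian noise SD (log2 units).
#' @param n_core_per_module high-loading core genes per module.
#' @param core_loading loading of core genes (their noise SD is
#'   sqrt(1 - core_loading^2), giving eigengene correlation ~ core_loading).
#' @param ppi_clique_size size of the planted interaction clique (drawn
#'   from module 1 cores).
#' @param ffl_spec list with `mirna`, `tfs` (two), and optionally `gene`
#'   (defaults to the first planted clique gene).
#' @param hazard_coeff log hazard ratio per unit of the prognostic
#'   covariate in the survival simulation.
#' @param seed integer master seed; generator substreams use fixed offsets.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000,
                       n_pairs_per_dataset = c(50, 50),
                       de_fraction = 0.2,
                       de_effect = 2.0,
                       n_modules = 3,
                       module_sizes = c(80, 60, 50),
                       factor_loading = 0.9,
                       noise_sd = 0.5,
                       n_core_per_module = 10,
                       core_loading = 0.98,
                       ppi_clique_size = 5,
                       ffl_spec = list(mirna = "hsa-miR-501-5p",
                                       tfs = c("TFX1", "TFX2"),
                                       gene = NULL),
                       hazard_coeff = log(2),
                       seed = 1) {
  stopifnot(n_genes >= 2, all(n_pairs_per_dataset >= 2),
            length(n_pairs_per_dataset) >= 1,
            de_fraction >= 0, de_fraction <= 1,
            de_effect >= 0, noise_sd > 0,
            factor_loading > 0, factor_loading < 1,
            core_loading > 0, core_loading < 1,
            n_modules == length(module_sizes))
  if (n_modules > 0) {
    if (any(module_sizes < 2)) stop("module sizes must be at least 2")
    if (sum(module_sizes) > n_genes)
      stop("module sizes sum to more than n_genes")
    if (any(module_sizes < n_core_per_module))
      stop("each module must hold its core genes")
    if (ppi_clique_size > n_core_per_module)
      stop("planted clique must fit inside module-1 core genes")
  }
  if (round(de_fraction * n_genes) < 1 && de_fraction > 0)
    stop("de_fraction * n_genes must be at least 1")
  stopifnot(length(ffl_spec$tfs) == 2, !is.null(ffl_spec$mirna))
  structure(list(n_genes = n_genes,
                 n_pairs_per_dataset = n_pairs_per_dataset,
                 de_fraction = de_fraction, de_effect = de_effect,
                 n_modules = n_modules, module_sizes = module_sizes,
                 factor_loading = factor_loading, noise_sd = noise_sd,
                 n_core_per_module = n_core_per_module,
                 core_loading = core_loading,
                 ppi_clique_size = ppi_clique_size,
                 ffl_spec = ffl_spec, hazard_coeff = hazard_coeff,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# substream offsets; keeps the generators reproducible and independent
seed_offset <- c(expression = 0L, ppi = 101L, genesets = 202L,
                 regulatory = 303L, survival = 404L)

#' Simulate paired tumour/normal expression cohorts
#'
#' Generates one log2-scale gene-by-sample matrix per dataset. Each subject
#' contributes one tumour and one normal column; module genes follow a
#' single-latent-factor model (loading * factor + noise, so intra-module
#' correlation is approximately loading^2 at the default noise level); DE
#' genes get a +/- `de_effect` shift in tumour columns. Baselines are
#' shared across datasets with a small dataset-specific per-gene offset.
#'
#' @param config a [sim_config()].
#' @return list with `datasets` (each `expr` matrix + `samples` sheet) and
#'   `truth` (gene universe, DE sets, module assignment, planted clique,
#'   planted FFL, prognostic genes).
#' @export
simulate_paired_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + seed_offset[["expression"]])
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  loading <- stats::setNames(rep(0, config$n_genes), genes)
  noise <- stats::setNames(rep(config$noise_sd, config$n_genes), genes)
  module <- stats::setNames(rep(NA_character_, config$n_genes), genes)
  cores <- list()
  if (config$n_modules > 0) {
    members <- sample(genes, sum(config$module_sizes))
    split_idx <- rep(seq_len(config$n_modules), config$module_sizes)
    for (m in seq_len(config$n_modules)) {
      gm <- members[split_idx == m]
      module[gm] <- paste0("M", m)
      core <- gm[seq_len(config$n_core_per_module)]
      cores[[m]] <- core
      loading[gm] <- config$factor_loading
      loading[core] <- config$core_loading
      noise[core] <- sqrt(1 - config$core_loading^2)
    }
  }
  # DE genes: module genes first (module direction alternates up/down),
  # then background genes with alternating signs
  n_de <- round(config$de_fraction * config$n_genes)
  de_sign <- stats::setNames(numeric(0), character(0))
  mod_dir <- function(m) if (m %% 2 == 1) 1 else -1
  if (n_de > 0) {
    pool_mod <- unlist(lapply(seq_along(cores), function(m)
      names(module)[!is.na(module) & module == paste0("M", m)]))
    take_mod <- utils::head(pool_mod, n_de)
    de_sign <- stats::setNames(
      vapply(take_mod, function(g) mod_dir(as.integer(sub("M", "", module[g]))),
             numeric(1)), take_mod)
    extra <- n_de - length(take_mod)
    if (extra > 0) {
      bg <- sample(genes[is.na(module)], extra)
      de_sign <- c(de_sign, stats::setNames(rep_len(c(1, -1), extra), bg))
    }
  }
  baseline <- stats::setNames(stats::runif(config$n_genes, 4, 12), genes)
  datasets <- lapply(seq_along(config$n_pairs_per_dataset), function(d) {
    P <- config$n_pairs_per_dataset[d]
    offs <- stats::rnorm(config$n_genes, 0, 0.3)
    subj <- sprintf("ds%d_s%03d", d, seq_len(P))
    tum <- paste0(subj, "_T")
    nor <- paste0(subj, "_N")
    cols <- c(tum, nor)
    expr <- matrix(stats::rnorm(config$n_genes * 2 * P, 0, 1),
                   nrow = config$n_genes) * noise
    expr <- expr + baseline + offs
    dimnames(expr) <- list(genes, cols)
    if (config$n_modules > 0) {
      fac <- matrix(stats::rnorm(config$n_modules * 2 * P),
                    nrow = config$n_modules)
      for (m in seq_len(config$n_modules)) {
        gm <- names(module)[!is.na(module) & module == paste0("M", m)]
        expr[gm, ] <- expr[gm, ] + outer(loading[gm], fac[m, ])
      }
    }
    if (length(de_sign) > 0) {
      expr[names(de_sign), tum] <-
        expr[names(de_sign), tum] + config$de_effect * de_sign
    }
    samples <- data.frame(sample_id = cols,
                          subject_id = rep(subj, 2),
                          condition = rep(c("tumor", "normal"), each = P),
                          dataset_id = paste0("ds", d))
    list(expr = expr, samples = samples)
  })
  clique <- if (config$n_modules > 0) cores[[1]][seq_len(config$ppi_clique_size)] else character(0)
  ffl <- config$ffl_spec
  if (is.null(ffl$gene)) {
    if (length(clique) == 0)
      stop("ffl_spec$gene must be supplied when no modules are planted")
    ffl$gene <- clique[1]
  }
  ffl_edges <- rbind(
    data.frame(source = ffl$mirna, target = ffl$gene, type = "miRNA-gene"),
    data.frame(source = ffl$mirna, target = ffl$tfs, type = "miRNA-TF"),
    data.frame(source = ffl$tfs, target = ffl$gene, type = "TF-gene"))
  truth <- structure(list(
    universe = genes,
    de_genes_up = names(de_sign)[de_sign > 0],
    de_genes_down = names(de_sign)[de_sign < 0],
    module_assignment = module[!is.na(module)],
    planted_clique = clique,
    planted_ffl = list(mirna = ffl$mirna, tfs = ffl$tfs, gene = ffl$gene,
                       edges = ffl_edges),
    prognostic_genes = stats::setNames(rep(1, length(clique)), clique),
    config = config), class = "ground_truth")
  list(datasets = datasets, truth = truth)
}

#' Simulate a scored interaction network with a planted clique
#'
#' The planted clique is fully connected with scores above the confidence
#' threshold; the background is Erdos-Renyi over all remaining node pairs
#' with scores drawn from a sub- and supra-threshold mixture.
#'
#' @param truth a `ground_truth` with a nonempty planted clique (>= 3).
#' @param n_background number of background nodes drawn from the universe.
#' @param background_edge_prob Erdos-Renyi edge probability.
#' @param seed integer seed (defaults to the config seed plus a fixed
#'   offset).
#' @param clique_score_range score range for clique edges (above the 0.9
#'   confidence threshold).
#' @param background_score_range score range for background edges.
#' @return a `weighted_graph` edge table (unthresholded).
#' @export
simulate_ppi_graph <- function(truth, n_background = 60,
                               background_edge_prob = 0.05, seed = NULL,
                               clique_score_range = c(0.95, 1),
                               background_score_range = c(0.5, 1)) {
  clique <- truth$planted_clique
  if (length(clique) < 3) stop("planted clique must have at least 3 nodes")
  set.seed(seed %||% (truth$config$seed + seed_offset[["ppi"]]))
  bg <- sample(setdiff(truth$universe, clique), n_background)
  nodes <- c(clique, bg)
  cp <- t(utils::combn(clique, 2))
  edges <- data.frame(node_a = cp[, 1], node_b = cp[, 2],
                      score = stats::runif(nrow(cp), clique_score_range[1],
                                           clique_score_range[2]))
  ap <- t(utils::combn(nodes, 2))
  in_clique <- ap[, 1] %in% clique & ap[, 2] %in% clique
  ap <- ap[!in_clique, , drop = FALSE]
  take <- stats::runif(nrow(ap)) < background_edge_prob
  if (any(take)) {
    edges <- rbind(edges, data.frame(
      node_a = ap[take, 1], node_b = ap[take, 2],
      score = stats::runif(sum(take), background_score_range[1],
                           background_score_range[2])))
  }
  weighted_graph(edges)
}

#' Simulate gene-set libraries capturing the planted hub genes
#'
#' At least `n_planted` terms contain the whole planted-clique-and-DE gene
#' set (padded with random genes up to a size drawn from
#' `term_size_range`); the remaining terms are random draws from the
#' universe.
#'
#' @param truth a `ground_truth`.
#' @param n_terms total number of terms.
#' @param term_size_range integer range of term sizes (>= 2).
#' @param seed integer seed (defaults to config seed plus a fixed offset).
#' @param n_planted number of terms capturing the planted set (default 2).
#' @param label library label.
#' @return a `gene_set_library`.
#' @export
simulate_genesets <- function(truth, n_terms = 20, term_size_range = c(10, 40),
                              seed = NULL, n_planted = 2, label = "synthetic") {
  stopifnot(n_terms >= n_planted, term_size_range[1] >= 2)
  if (term_size_range[2] > length(truth$universe))
    stop("term size exceeds the gene universe")
  set.seed(seed %||% (truth$config$seed + seed_offset[["genesets"]]))
  planted_set <- intersect(truth$planted_clique,
                           c(truth$de_genes_up, truth$de_genes_down))
  terms <- list()
  for (i in seq_len(n_planted)) {
    size <- sample(seq(max(term_size_range[1], length(planted_set)),
                       term_size_range[2]), 1)
    pad <- sample(setdiff(truth$universe, planted_set),
                  size - length(planted_set))
    terms[[sprintf("%s_PLANTED_%02d", toupper(label), i)]] <-
      sort(c(planted_set, pad))
  }
  for (i in seq_len(n_terms - n_planted)) {
    size <- sample(seq(term_size_range[1], term_size_range[2]), 1)
    terms[[sprintf("%s_TERM_%02d", toupper(label), i)]] <-
      sort(sample(truth$universe, size))
  }
  gene_set_library(terms, label = label)
}

#' Simulate regulatory edge tables, screen lists and decoys
#'
#' Planted feed-forward-loop edges carry filter-passing annotations (miRNA
#' target score above 0.95 in the 3'UTR; TF p below 0.001), the planted
#' regulators appear on the tier-1 list and (for the miRNA) in the mouse
#' tables. Each decoy edge fails exactly one barrier, cycling through: low
#' score, wrong binding region, large TF p-value, absence from the tier-1
#' list, and absence from the mouse tables.
#'
#' @param truth a `ground_truth` with a planted FFL.
#' @param n_decoys number of decoy regulators.
#' @param seed integer seed (defaults to config seed plus a fixed offset).
#' @return list with `mirna_gene`, `tf_gene`, `mirna_tf` (human tables),
#'   `mouse_mirna_gene`, `mouse_mirna_tf`, and `tier1`.
#' @export
simulate_regulatory_tables <- function(truth, n_decoys = 10, seed = NULL) {
  set.seed(seed %||% (truth$config$seed + seed_offset[["regulatory"]]))
  ffl <- truth$planted_ffl
  pass_edge <- function(source, target, type, species = "human") {
    mirna_edge <- type %in% c("miRNA-gene", "miRNA-TF")
    data.frame(source = source, target = target, type = type,
               score = if (mirna_edge) stats::runif(length(source), 0.96, 0.995) else NA_real_,
               binding_region = if (mirna_edge) "3'UTR" else NA_character_,
               p_value = if (mirna_edge) NA_real_ else stats::runif(length(source), 1e-5, 5e-4),
               species = species)
  }
  mirna_gene <- pass_edge(ffl$mirna, ffl$gene, "miRNA-gene")
  mirna_tf <- pass_edge(ffl$mirna, ffl$tfs, "miRNA-TF")
  tf_gene <- pass_edge(ffl$tfs, ffl$gene, "TF-gene")
  mmu <- function(x) sub("^hsa-", "mmu-", x)
  mouse_mirna_gene <- pass_edge(mmu(ffl$mirna), ffl$gene, "miRNA-gene", "mouse")
  mouse_mirna_tf <- pass_edge(mmu(ffl$mirna), ffl$tfs, "miRNA-TF", "mouse")
  tier1 <- c(ffl$mirna, ffl$tfs)
  hub_targets <- if (length(truth$planted_clique) > 0) truth$planted_clique else ffl$gene
  fail_modes <- c("low_score", "bad_region", "high_p", "no_tier1", "no_mouse")
  for (i in seq_len(n_decoys)) {
    mode <- fail_modes[(i - 1) %% length(fail_modes) + 1]
    target <- hub_targets[(i - 1) %% length(hub_targets) + 1]
    if (mode == "high_p") {
      dec <- sprintf("DECTF%02d", i)
      if (dec %in% c(ffl$tfs)) stop("decoy identifier collides with a planted TF")
      e <- pass_edge(dec, target, "TF-gene")
      e$p_value <- stats::runif(1, 0.01, 0.5)
      tf_gene <- rbind(tf_gene, e)
      tier1 <- c(tier1, dec)
    } else {
      dec <- sprintf("hsa-miR-dec%02d", i)
      if (normalize_mirna(dec) == normalize_mirna(ffl$mirna))
        stop("decoy identifier collides with the planted miRNA")
      e <- pass_edge(dec, target, "miRNA-gene")
      if (mode == "low_score") e$score <- stats::runif(1, 0.2, 0.9)
      if (mode == "bad_region") e$binding_region <- "5'UTR"
      mirna_gene <- rbind(mirna_gene, e)
      if (mode != "no_tier1") tier1 <- c(tier1, dec)
      if (mode != "no_mouse") {
        mouse_mirna_gene <- rbind(mouse_mirna_gene,
                                  pass_edge(mmu(dec), target, "miRNA-gene", "mouse"))
      }
    }
  }
  list(mirna_gene = mirna_gene, tf_gene = tf_gene, mirna_tf = mirna_tf,
       mouse_mirna_gene = mouse_mirna_gene, mouse_mirna_tf = mouse_mirna_tf,
       tier1 = unique(tier1))
}

#' Simulate a survival table with expression-dependent hazard
#'
#' Event times are exponential with a baseline scale; for prognostic genes
#' the hazard is multiplied by exp(hazard_coeff * z). With
#' `effect = "binary"` (default) z is the above-median indicator of a
#' shared latent severity, so the median-split Mantel-Haenszel hazard ratio
#' targets exp(hazard_coeff) directly; with `effect = "linear"` z is the
#' centred log2 expression of the first prognostic gene. Censoring is
#' independent: each subject is censored with probability `censor_rate` at
#' a uniform fraction of its event time.
#'
#' @param truth a `ground_truth` with nonempty prognostic genes.
#' @param n_subjects number of subjects (>= 20).
#' @param baseline_scale exponential baseline mean survival (months, > 0).
#' @param censor_rate probability a subject is censored.
#' @param seed integer seed (defaults to config seed plus a fixed offset).
#' @param effect `"binary"` or `"linear"` hazard covariate (see above).
#' @return data.frame: `subject_id`, `time_months`, `event`, one expression
#'   column per prognostic gene.
#' @export
simulate_survival <- function(truth, n_subjects = 200, baseline_scale = 60,
                              censor_rate = 0.2, seed = NULL,
                              effect = c("binary", "linear")) {
  effect <- match.arg(effect)
  genes <- names(truth$prognostic_genes)
  if (length(genes) == 0) stop("no prognostic genes in the ground truth")
  if (n_subjects < 20) stop("at least 20 subjects are required")
  if (baseline_scale <= 0) stop("baseline scale must be positive")
  stopifnot(censor_rate >= 0, censor_rate < 1)
  set.seed(seed %||% (truth$config$seed + seed_offset[["survival"]]))
  b <- stats::rbinom(n_subjects, 1, 0.5)
  expr <- sapply(genes, function(g)
    8 + 2 * b * truth$prognostic_genes[[g]] + stats::rnorm(n_subjects, 0, 0.4))
  z <- if (effect == "binary") b else expr[, 1] - mean(expr[, 1])
  rate <- exp(truth$config$hazard_coeff * z) / baseline_scale
  ev_time <- stats::rexp(n_subjects, rate = rate)
  cen <- stats::rbinom(n_subjects, 1, censor_rate) == 1
  time <- ifelse(cen, pmax(stats::runif(n_subjects) * ev_time, 1e-6), ev_time)
  out <- data.frame(subject_id = sprintf("S%04d", seq_len(n_subjects)),
                    time_months = time, event = as.integer(!cen))
  cbind(out, as.data.frame(expr))
}

#' Generate and write the full synthetic input bundle
#'
#' Runs every generator with seeds derived from the config seed and writes
#' the complete set of pipeline inputs as plain-text files into `dir`:
#' per-dataset expression/sample-sheet TSVs, the scored interaction edge
#' table, two GMT libraries, the human and mouse regulatory tables, the
#' tier-1 screen list, the survival table and the ground truth as JSON.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @param n_survival_subjects subjects in the survival table.
#' @return list with `dir`, `truth` and the named file `paths`, invisibly.
#' @export
simulate_bundle <- function(config, dir, n_survival_subjects = 200) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_paired_expression(config)
  truth <- sim$truth
  paths <- list(expr = character(0), samples = character(0))
  for (d in seq_along(sim$datasets)) {
    pe <- file.path(dir, sprintf("expr_ds%d.tsv", d))
    ps <- file.path(dir, sprintf("samples_ds%d.tsv", d))
    write_expression_tsv(sim$datasets[[d]]$expr, pe)
    write_tsv(sim$datasets[[d]]$samples, ps)
    paths$expr <- c(paths$expr, pe)
    paths$samples <- c(paths$samples, ps)
  }
  ppi <- simulate_ppi_graph(truth)
  paths$ppi <- file.path(dir, "ppi_edges.tsv")
  write_tsv(stats::setNames(as.data.frame(ppi),
                            c("protein1", "protein2", "combined_score")),
            paths$ppi)
  gmt1 <- simulate_genesets(truth, seed = config$seed + seed_offset[["genesets"]],
                            label = "go_bp")
  gmt2 <- simulate_genesets(truth, seed = config$seed + seed_offset[["genesets"]] + 1,
                            label = "pathway")
  paths$gmt <- file.path(dir, c("genesets_go_bp.gmt", "genesets_pathway.gmt"))
  write_gmt(gmt1, paths$gmt[1])
  write_gmt(gmt2, paths$gmt[2])
  reg <- simulate_regulatory_tables(truth)
  for (nm in c("mirna_gene", "tf_gene", "mirna_tf",
               "mouse_mirna_gene", "mouse_mirna_tf")) {
    paths[[nm]] <- file.path(dir, paste0(nm, ".tsv"))
    write_tsv(reg[[nm]], paths[[nm]])
  }
  paths$tier1 <- file.path(dir, "tier1.txt")
  writeLines(reg$tier1, paths$tier1)
  surv <- simulate_survival(truth, n_subjects = n_survival_subjects)
  paths$survival <- file.path(dir, "survival.tsv")
  write_tsv(surv, paths$survival)
  paths$truth <- file.path(dir, "truth.json")
  jsonlite::write_json(truth[setdiff(names(truth), "config")], paths$truth,
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(list(dir = dir, truth = truth, paths = paths))
}
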