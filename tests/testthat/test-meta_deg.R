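make_paired <- function(diffs, base = 5) {
  # one gene per row of diffs; tumor = normal + diff per subject
  n <- ncol(diffs)
  normal <- matrix(base, nrow = nrow(diffs), ncol = n)
  expr <- cbind(normal + diffs, normal)
  rownames(expr) <- rownames(diffs) %||% paste0("g", seq_len(nrow(diffs)))
  colnames(expr) <- c(paste0("s", 1:n, "_T"), paste0("s", 1:n, "_N"))
  samples <- data.frame(sample_id = colnames(expr),
                        subject_id = rep(paste0("s", 1:n), 2),
                        condition = rep(c("tumor", "normal"), each = n),
                        dataset_id = "ds1")
  list(expr = expr, samples = samples)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("probe collapsing averages duplicate symbols and drops unmapped probes", {
  pm <- matrix(c(2, 4, 10, 7), nrow = 4, ncol = 2,
               dimnames = list(c("p1", "p2", "p3", "p4"), c("s1", "s2")))
  ann <- data.frame(probe_id = c("p1", "p2", "p3", "p4"),
                    symbol = c("G", "G", "B", NA))
  out <- collapse_probes(pm, ann)
  expect_equal(rownames(out), c("B", "G"))          # lexicographic
  expect_equal(unname(out["G", "s1"]), mean(c(2, 4)))
  expect_false("p4" %in% rownames(out))
  # hand-computed fixture: 3 probes -> 2 genes
  pm2 <- matrix(1:6, nrow = 3, dimnames = list(c("a", "b", "c"), c("x", "y")))
  out2 <- collapse_probes(pm2, c(a = "G1", b = "G1", c = "G2"))
  expect_equal(nrow(out2), 2)
  expect_equal(unname(out2["G1", ]), c(mean(1:2), mean(4:5)))
  expect_error(collapse_probes(pm2, c(a = NA, b = "", c = NA)), "no probes")
})

test_that("gene intersection aligns matrices on the sorted common gene set", {
  m1 <- matrix(1, 3, 2, dimnames = list(c("A", "B", "C"), c("x", "y")))
  m2 <- matrix(2, 3, 2, dimnames = list(c("D", "C", "B"), c("u", "v")))
  out <- intersect_genes(list(m1, m2))
  expect_equal(rownames(out[[1]]), c("B", "C"))
  expect_equal(rownames(out[[2]]), c("B", "C"))
  expect_identical(intersect_genes(list(m1, m1))[[1]], m1)
  m3 <- matrix(3, 2, 2, dimnames = list(c("X", "Y"), c("u", "v")))
  expect_error(intersect_genes(list(m1, m3)), "common")
})

test_that("paired t matches the Student-t closed form", {
  d <- rbind(g1 = c(1, 2, 3), g2 = c(-1, 1, 0))
  fx <- make_paired(d)
  res <- paired_t_test(fx$expr, fx$samples)
  expect_equal(res$t[1], 2 / (1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(res$t[1], 3.4641, tolerance = 1e-4)
  expect_equal(res$df[1], 2)
  expect_equal(res$p[1], 2 * pt(3.4641016, df = 2, lower.tail = FALSE),
               tolerance = 1e-7)
  expect_equal(res$p[1], 0.0742, tolerance = 1e-3)
  # cross-check against stats::t.test on the same differences
  tt <- t.test(c(1, 2, 3))
  expect_equal(res$p[1], tt$p.value, tolerance = 1e-12)
})

test_that("zero-variance and antisymmetric difference edge cases", {
  fx <- make_paired(rbind(gz = c(2, 2), ga = c(-1, 1)))
  expect_message(res <- paired_t_test(fx$expr, fx$samples), "zero-variance")
  expect_true(is.na(res$p[res$gene == "gz"]))
  expect_equal(res$t[res$gene == "ga"], 0)
  expect_equal(res$p[res$gene == "ga"], 1)
})

test_that("Fisher combination matches the chi-squared closed form", {
  # (1, 1) -> X = 0, p = 1
  r <- fisher_combine(matrix(c(1, 1), nrow = 1))
  expect_equal(r$X, 0)
  expect_equal(r$p_combined, 1)
  # (0.05, 0.05) -> X ~ 11.983, p ~ 0.01747 against chi^2_4
  r2 <- fisher_combine(matrix(c(0.05, 0.05), nrow = 1))
  expect_equal(r2$X, -4 * log(0.05), tolerance = 1e-12)
  expect_equal(r2$X, 11.983, tolerance = 1e-3)
  expect_equal(r2$p_combined, pchisq(-4 * log(0.05), 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(r2$p_combined, 0.01747, tolerance = 1e-3)
  # p = 0 is clamped, not infinite
  r3 <- fisher_combine(matrix(c(0, 0.5), nrow = 1))
  expect_true(is.finite(r3$X))
  expect_error(fisher_combine(matrix(c(-0.1, 0.5), nrow = 1)), "0, 1")
})

test_that("single-dataset Fisher combination is the identity (chi^2_2 closed form)", {
  set.seed(41)
  p <- runif(1000)
  r <- fisher_combine(matrix(p, ncol = 1))
  expect_equal(r$p_combined, p, tolerance = 1e-12)
})

test_that("BH adjustment matches the min-over-tail oracle and handles NA", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.2, 0.2, 0.2)), c(0.2, 0.2, 0.2))
  expect_equal(bh_adjust(0.07), 0.07)
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  set.seed(42)
  for (i in 1:50) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
  # NA entries are excluded from m, not counted as tests
  p <- c(0.01, NA, 0.04)
  expect_equal(bh_adjust(p), c(0.02, NA, 0.04))
})

test_that("log2 fold change pools tumor and normal samples across datasets", {
  fx1 <- make_paired(rbind(g1 = c(1, 1)))         # per-dataset FC 1
  fx2 <- make_paired(rbind(g1 = c(3, 3)))         # per-dataset FC 3
  out <- compute_log2fc(list(fx1$expr, fx2$expr),
                        list(fx1$samples, fx2$samples))
  expect_equal(out$log2fc, 2)                      # pooled with equal n
  expect_equal(out$log2fc_ds1, 1)
  expect_equal(out$log2fc_ds2, 3)
  fx0 <- make_paired(rbind(g1 = c(0, 0)))
  expect_equal(compute_log2fc(list(fx0$expr), list(fx0$samples))$log2fc, 0)
})

test_that("meta-DEG classification uses strict thresholds", {
  tab <- data.frame(p_bh = rep(1e-5, 4), log2fc = c(1.6, -1.6, 1.5, -1.5))
  out <- call_meta_degs(tab)
  expect_equal(out$class, c("up", "down", "not_significant", "not_significant"))
  tab2 <- data.frame(p_bh = 1e-4, log2fc = 3)     # boundary p: not < alpha
  expect_equal(call_meta_degs(tab2)$class, "not_significant")
})

test_that("unlogged matrices are detected and log2-transformed with a warning", {
  fx <- make_paired(rbind(g1 = c(1, 1, 1), g2 = c(0, 0, 0)), base = 200)
  expect_warning(expect_warning(  # one warning per unlogged dataset
    res <- run_meta_deg(list(fx$expr, fx$expr), list(fx$samples, fx$samples)),
    "log2"), "log2")
  expect_true(all(res$table$log2fc < 1))
})
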