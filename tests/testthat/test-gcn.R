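# latent-factor module fixture: each module is loading * factor + noise
module_fixture <- function(sizes, loading = 0.9, noise = 0.5, n_samples = 60,
                           factor_cor = 0) {
  n <- sum(sizes)
  f0 <- matrix(rnorm(length(sizes) * n_samples), nrow = length(sizes))
  if (factor_cor > 0 && length(sizes) > 1) {
    shared <- rnorm(n_samples)
    f0 <- sqrt(factor_cor) * matrix(shared, nrow = length(sizes),
                                    ncol = n_samples, byrow = TRUE) +
      sqrt(1 - factor_cor) * f0
  }
  lab <- rep(seq_along(sizes), sizes)
  x <- loading * f0[lab, ] + matrix(rnorm(n * n_samples, 0, noise), nrow = n)
  rownames(x) <- sprintf("g%03d", seq_len(n))
  colnames(x) <- sprintf("s%03d", seq_len(n_samples))
  list(x = x, truth = setNames(paste0("M", lab), rownames(x)))
}

test_that("similarity matrix is the absolute Pearson correlation", {
  set.seed(1)
  x <- matrix(rnorm(15), nrow = 3,
              dimnames = list(c("a", "b", "c"), paste0("s", 1:5)))
  x["b", ] <- x["a", ]        # duplicate -> s = 1
  x["c", ] <- -x["a", ]       # anticorrelated -> s = 1 (absolute)
  S <- similarity_matrix(x)
  expect_equal(unname(S["a", "b"]), 1)
  expect_equal(unname(S["a", "c"]), 1)
  y <- matrix(rnorm(20), nrow = 4, dimnames = list(letters[1:4], NULL))
  expect_equal(unname(similarity_matrix(y)), unname(abs(cor(t(y)))))
  y[1, ] <- 7
  expect_error(similarity_matrix(y), "variance")
  expect_error(similarity_matrix(y[, 1:2, drop = FALSE]), "3 samples")
})

test_that("TOM matches hand computations and the brute-force oracle", {
  # unit-weight triangle: omega = (1 + 1)/(2 + 1 - 1) = 1
  A3 <- matrix(1, 3, 3) - diag(3)
  expect_true(all(abs(tom_matrix(A3) - 1) < 1e-12))
  # isolated pair with a = 0.5: omega = (0 + 0.5)/(0.5 + 1 - 0.5) = 0.5
  A2 <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  expect_equal(tom_matrix(A2)[1, 2], 0.5)
  # empty graph: zero off-diagonal
  A0 <- matrix(0, 4, 4)
  expect_true(all(tom_matrix(A0)[upper.tri(A0)] == 0))
  set.seed(7)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    A <- matrix(runif(n * n), n)
    A <- (A + t(A)) / 2
    diag(A) <- 0
    expect_equal(tom_matrix(A), oracle_tom(A), tolerance = 1e-12)
  }
  expect_error(tom_matrix(A2 - 1), "non-negative")
})

test_that("adjacency is monotone non-increasing in the soft power", {
  set.seed(8)
  x <- matrix(rnorm(200), nrow = 20)
  rownames(x) <- paste0("g", 1:20)
  S <- similarity_matrix(x)
  for (b in 1:6) {
    expect_true(all(adjacency_matrix(S, b + 1) <= adjacency_matrix(S, b) + 1e-15))
  }
})

test_that("scale-free fit scores an exact power-law degree sequence highly", {
  set.seed(9)
  u <- runif(2000)
  k <- 1 * u^(-1 / 1.5)            # Pareto sample, alpha = 2.5
  fit <- coexffl:::scale_free_fit(k, n_bins = 10)
  expect_gt(fit$signed_r2, 0.9)
  expect_lt(fit$slope, 0)
})

test_that("soft-threshold selection falls back to the argmax with a warning", {
  set.seed(10)
  fx <- module_fixture(c(20, 20), n_samples = 40)
  S <- similarity_matrix(fx$x)
  expect_warning(st <- pick_soft_threshold(S, powers = 1:6, target_r2 = 0.999),
                 "argmax")
  expect_false(st$reached_target)
  expect_equal(st$beta, st$fits$power[which.max(st$fits$signed_r2)])
  Sc <- matrix(0.5, 40, 40)
  diag(Sc) <- 1
  expect_error(pick_soft_threshold(Sc), "degenerate")
  expect_error(pick_soft_threshold(S[1:10, 1:10]), "30 genes")
})

test_that("dendrogram cutting recovers well-separated planted blocks exactly", {
  blocks <- c(35, 35)
  D <- matrix(0.9, sum(blocks), sum(blocks))
  lab <- rep(1:2, blocks)
  D[lab == 1, lab == 1] <- 0.1
  D[lab == 2, lab == 2] <- 0.1
  diag(D) <- 0
  dimnames(D) <- list(sprintf("g%02d", seq_len(sum(blocks))),
                      sprintf("g%02d", seq_len(sum(blocks))))
  part <- cluster_and_cut(D, min_module_size = 30)
  expect_equal(length(setdiff(unique(part$labels), "grey")), 2)
  expect_equal(ari(part$labels, lab), 1)
  # all-identical genes: a single module
  D0 <- matrix(0, 40, 40, dimnames = list(paste0("g", 1:40), paste0("g", 1:40)))
  p0 <- cluster_and_cut(D0, min_module_size = 30)
  expect_equal(length(unique(p0$labels)), 1)
  expect_false("grey" %in% p0$labels)
  # fewer genes than the minimum size: everything grey
  expect_warning(pg <- cluster_and_cut(D0[1:10, 1:10], min_module_size = 30),
                 "grey")
  expect_true(all(pg$labels == "grey"))
})

test_that("module eigengenes are unit variance, oriented, and track the factor", {
  set.seed(11)
  fx <- module_fixture(c(40, 40), loading = 0.9, noise = 0.3, n_samples = 80)
  ME <- module_eigengenes(fx$x, fx$truth)
  expect_equal(apply(ME, 2, sd), c(M1 = 1, M2 = 1), tolerance = 1e-10)
  # identical profiles: |cor(ME, x)| = 1
  xx <- matrix(rep(rnorm(30), each = 3), nrow = 3,
               dimnames = list(c("a", "b", "c"), NULL))
  xx <- xx + matrix(rnorm(90, 0, 1e-8), nrow = 3)
  ME1 <- module_eigengenes(xx, setNames(rep("M1", 3), rownames(xx)))
  expect_equal(abs(cor(ME1[, 1], xx[1, ])), 1, tolerance = 1e-6)
  # orientation: flipping all genes leaves |kME| unchanged
  MEf <- module_eigengenes(-fx$x, fx$truth)
  expect_equal(abs(cor(fx$x[1, ], ME[, "M1"])), abs(cor(-fx$x[1, ], MEf[, "M1"])),
               tolerance = 1e-10)
  # eigengene correlates strongly with the planted factor's best proxy
  expect_gt(abs(cor(ME[, "M1"], rowMeans(scale(t(fx$x[fx$truth == "M1", ]))))), 0.95)
  expect_error(module_eigengenes(fx$x, setNames(c("M1", rep("grey", 79)),
                                                rownames(fx$x))), "single gene")
})

test_that("eigengene merging joins modules above the correlation threshold", {
  set.seed(12)
  # factor_cor controls cor(ME_i, ME_j): 0.9 merges, 0.5 does not
  hi <- module_fixture(c(30, 30), loading = 0.98, noise = 0.1,
                       n_samples = 300, factor_cor = 0.9)
  m_hi <- merge_close_modules(hi$x, hi$truth, merge_height = 0.2)
  expect_equal(length(setdiff(unique(m_hi$labels), "grey")), 1)
  lo <- module_fixture(c(30, 30), loading = 0.98, noise = 0.1,
                       n_samples = 300, factor_cor = 0.5)
  m_lo <- merge_close_modules(lo$x, lo$truth, merge_height = 0.2)
  expect_equal(length(setdiff(unique(m_lo$labels), "grey")), 2)
  # three near-identical modules collapse to one by iteration
  tri <- module_fixture(c(30, 30, 30), loading = 0.98, noise = 0.1,
                        n_samples = 300, factor_cor = 0.97)
  m_tri <- merge_close_modules(tri$x, tri$truth, merge_height = 0.2)
  expect_equal(length(setdiff(unique(m_tri$labels), "grey")), 1)
})

test_that("connectivity table satisfies its identities and matches brute force", {
  set.seed(13)
  fx <- module_fixture(c(35, 35), loading = 0.9, noise = 0.4, n_samples = 60)
  S <- similarity_matrix(fx$x)
  A <- adjacency_matrix(S, 6)
  TOM <- tom_matrix(A)
  ct <- connectivity_table(A, TOM, fx$x, fx$truth)
  assigned <- ct$module != "grey"
  expect_equal(ct$k.in[assigned] + ct$kOut[assigned], ct$kTotal[assigned],
               tolerance = 1e-10)
  expect_equal(ct$kDiff, ct$k.in - ct$kOut, tolerance = 1e-10)
  expect_true(all(abs(ct$MM[assigned]) <= 1))
  # brute-force check of one gene's sums
  g <- ct$gene[assigned][1]
  members <- ct$gene[ct$module == ct$module[ct$gene == g]]
  expect_equal(ct$k.in[ct$gene == g],
               sum(A[g, setdiff(members, g)]), tolerance = 1e-10)
  expect_equal(ct$kTotal[ct$gene == g],
               sum(A[g, setdiff(rownames(A), g)]), tolerance = 1e-10)
  expect_equal(ct$omega.in[ct$gene == g],
               sum(TOM[g, setdiff(members, g)]), tolerance = 1e-10)
})

test_that("a unit-weight complete module has k.in = n - 1", {
  n <- 4
  x <- matrix(rep(rnorm(30), each = n), nrow = n) +
    matrix(rnorm(n * 30, 0, 1e-6), nrow = n)
  rownames(x) <- paste0("g", 1:n)
  A <- adjacency_matrix(similarity_matrix(x), 1)
  TOM <- tom_matrix(A)
  ct <- connectivity_table(A, TOM, x, setNames(rep("M1", n), rownames(x)))
  expect_equal(ct$k.in, rep(n - 1, n), tolerance = 1e-3)
  expect_equal(ct$MM, rep(1, n), tolerance = 1e-3)
})

test_that("representative screening keeps only high-loading genes (strict MM > 0.9)", {
  set.seed(14)
  n_hi <- 20; n_lo <- 20
  f <- rnorm(400)
  x <- rbind(0.98 * matrix(f, n_hi, 400, byrow = TRUE) +
               matrix(rnorm(n_hi * 400, 0, sqrt(1 - 0.98^2)), n_hi),
             0.80 * matrix(f, n_lo, 400, byrow = TRUE) +
               matrix(rnorm(n_lo * 400, 0, 0.6), n_lo))
  rownames(x) <- c(sprintf("hi%02d", 1:n_hi), sprintf("lo%02d", 1:n_lo))
  lab <- setNames(rep("M1", nrow(x)), rownames(x))
  A <- adjacency_matrix(similarity_matrix(x), 6)
  ct <- connectivity_table(A, tom_matrix(A), x, lab)
  rep_set <- representative_genes(ct)$M1
  expect_setequal(rep_set, sprintf("hi%02d", 1:n_hi))
  # boundary is strict
  tab <- data.frame(gene = c("a", "b"), module = "M1", MM = c(0.95, 0.9))
  expect_equal(representative_genes(tab)$M1, "a")
})

test_that("full co-expression run recovers planted modules (ARI >= 0.8) deterministically", {
  set.seed(15)
  fx <- module_fixture(c(35, 35, 35), loading = 0.9, noise = 0.5, n_samples = 80)
  g1 <- suppressWarnings(run_gcn(fx$x, powers = 1:10))
  expect_gte(ari(g1$labels[names(fx$truth)], fx$truth), 0.8)
  g2 <- suppressWarnings(run_gcn(fx$x, powers = 1:10))
  expect_identical(g1$labels, g2$labels)
  expect_identical(g1$eigengenes, g2$eigengenes)
})
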