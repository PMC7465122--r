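mirna_edge <- function(source, target, type = "miRNA-gene", score = 0.97,
                       region = "3'UTR") {
  data.frame(source = source, target = target, type = type, score = score,
             binding_region = region, p_value = NA_real_, species = "human")
}
tf_edge <- function(source, target, p = 1e-4) {
  data.frame(source = source, target = target, type = "TF-gene",
             score = NA_real_, binding_region = NA_character_, p_value = p,
             species = "human")
}

test_that("edge filters apply strict thresholds and region normalisation", {
  e <- rbind(mirna_edge("m1", "G1", score = 0.96),
             mirna_edge("m2", "G1", score = 0.95),        # boundary: dropped
             mirna_edge("m3", "G1", score = 0.99, region = "5'UTR"),
             mirna_edge("m4", "G1", score = 0.99, region = "3UTR"),
             tf_edge("t1", "G1", p = 5e-4),
             tf_edge("t2", "G1", p = 0.001),               # boundary: dropped
             mirna_edge("m1", "G1", score = 0.96))         # duplicate
  out <- filter_regulatory_edges(e)
  expect_setequal(out$source, c("m1", "m4", "t1"))
  expect_equal(sum(out$source == "m1"), 1)
  expect_error(filter_regulatory_edges(data.frame(source = "a", target = "b",
                                                  type = "weird")), "unknown")
})

test_that("the two-tier screen keeps only literature-plus-mouse-conserved miRNAs", {
  e <- rbind(mirna_edge("hsa-miR-1-5p", "G1"),
             mirna_edge("hsa-miR-2-5p", "G1"),
             mirna_edge("hsa-miR-3-5p", "G1"),
             tf_edge("TF1", "G1"), tf_edge("TF2", "G1"))
  mouse <- rbind(mirna_edge("mmu-miR-1-5p", "G1"),
                 mirna_edge("mmu-miR-3-5p", "G1"))
  tier1 <- c("hsa-miR-1-5p", "hsa-miR-2-5p", "TF1")
  out <- two_tier_screen(e, tier1, mouse)
  # miR-1: tier1 + mouse -> kept; miR-2: tier1 only -> dropped;
  # miR-3: mouse only -> dropped; TF1 on tier1 alone; TF2 dropped
  expect_setequal(out$source, c("hsa-miR-1-5p", "TF1"))
  expect_warning(none <- two_tier_screen(e, character(0), mouse), "tier-1")
  expect_equal(nrow(none), 0)
})

test_that("filter and screen commute", {
  set.seed(41)
  e <- rbind(mirna_edge(paste0("hsa-miR-", 1:6), "G1",
                        score = runif(6, 0.9, 1),
                        region = sample(c("3'UTR", "5'UTR"), 6, TRUE)),
             tf_edge(paste0("TF", 1:4), "G1", p = runif(4, 0, 0.01)))
  mouse <- mirna_edge(paste0("mmu-miR-", c(1, 2, 5)), "G1")
  tier1 <- c(paste0("hsa-miR-", c(1, 3, 5)), "TF1", "TF3")
  a <- two_tier_screen(filter_regulatory_edges(e), tier1, mouse)
  b <- filter_regulatory_edges(two_tier_screen(e, tier1, mouse))
  expect_equal(a[order(a$source, a$target), c("source", "target", "type")],
               b[order(b$source, b$target), c("source", "target", "type")],
               ignore_attr = TRUE)
})

test_that("network assembly reports Table-2-style node and edge bookkeeping", {
  # planted composite FFL alone: 4 nodes, 5 edges
  e <- rbind(mirna_edge("m1", "G1"),
             mirna_edge("m1", "T1", type = "miRNA-TF"),
             mirna_edge("m1", "T2", type = "miRNA-TF"),
             tf_edge("T1", "G1"), tf_edge("T2", "G1"))
  net <- assemble_ffl_network(e)
  expect_equal(net$n_nodes, 4)
  expect_equal(net$n_edges, 5)
  expect_equal(unname(net$edge_counts),
               c(1L, 2L, 2L))
  # empty input: empty network
  empty <- assemble_ffl_network(e[0, ])
  expect_equal(empty$n_nodes, 0L)
  expect_equal(empty$n_edges, 0L)
  # conflicting roles are rejected
  bad <- rbind(mirna_edge("m1", "X"), tf_edge("X", "G1"))
  expect_error(assemble_ffl_network(bad), "conflicting roles")
})

test_that("motif enumeration matches the brute-force triple loop", {
  set.seed(42)
  for (i in 1:30) {
    mirnas <- paste0("m", 1:sample(2:4, 1))
    tfs <- paste0("T", 1:sample(2:4, 1))
    genes <- paste0("G", 1:sample(2:4, 1))
    e <- rbind(
      mirna_edge(sample(mirnas, 6, TRUE), sample(genes, 6, TRUE)),
      mirna_edge(sample(mirnas, 6, TRUE), sample(tfs, 6, TRUE), type = "miRNA-TF"),
      tf_edge(sample(tfs, 6, TRUE), sample(genes, 6, TRUE)))
    net <- assemble_ffl_network(e)
    got <- ffl_motifs(net)
    want <- oracle_motifs(net)
    got_triples <- do.call(rbind, lapply(got, function(x)
      expand.grid(x$mirna, x$tfs, x$gene, stringsAsFactors = FALSE)))
    expect_equal(length(want),
                 if (is.null(got_triples)) 0L else nrow(got_triples))
    if (length(want) > 0) {
      key_w <- sort(vapply(want, paste, "", collapse = "|"))
      key_g <- sort(apply(got_triples, 1, paste, collapse = "|"))
      expect_equal(key_g, key_w)
    }
    # closure: every motif edge is present in the assembled network
    for (m in got) {
      for (r in seq_len(nrow(m$edges))) {
        expect_true(any(net$edges$source == m$edges$source[r] &
                          net$edges$target == m$edges$target[r] &
                          net$edges$type == m$edges$type[r]))
      }
    }
  }
})

test_that("the highest-order motif maximises summed node degree", {
  # two disjoint FFLs; the first has extra edges inflating its degrees
  e <- rbind(mirna_edge("m1", "G1"),
             mirna_edge("m1", "T1", type = "miRNA-TF"),
             tf_edge("T1", "G1"),
             mirna_edge("m1", "G2"), tf_edge("T1", "G2"),  # extra degree
             mirna_edge("m2", "G3"),
             mirna_edge("m2", "T2", type = "miRNA-TF"),
             tf_edge("T2", "G3"))
  net <- assemble_ffl_network(e)
  top <- highest_order_motif(net)
  expect_equal(top$mirna, "m1")
  # composite instance: one miRNA, two TFs, one gene
  e2 <- rbind(mirna_edge("m1", "G1"),
              mirna_edge("m1", "T1", type = "miRNA-TF"),
              mirna_edge("m1", "T2", type = "miRNA-TF"),
              tf_edge("T1", "G1"), tf_edge("T2", "G1"))
  top2 <- highest_order_motif(assemble_ffl_network(e2))
  expect_equal(top2$tfs, c("T1", "T2"))
  expect_equal(top2$n_tfs, 2)
  # open triangle (no miRNA->gene edge): no motif
  e3 <- rbind(mirna_edge("m1", "T1", type = "miRNA-TF"), tf_edge("T1", "G1"))
  expect_message(none <- highest_order_motif(assemble_ffl_network(e3)),
                 "no closed")
  expect_null(none)
})

test_that("the published summary-count reconstruction yields 21 nodes and 66 edges", {
  tabs <- table2_tables()
  expect_equal(nrow(tabs$mirna_gene), 19)
  expect_equal(nrow(tabs$tf_gene), 25)
  expect_equal(nrow(tabs$mirna_tf), 22)
  net <- assemble_ffl_network(rbind(tabs$mirna_gene, tabs$tf_gene, tabs$mirna_tf))
  expect_equal(net$n_nodes, 21)
  expect_equal(net$n_edges, 66)
  expect_equal(sum(net$nodes$role == "miRNA"), 11)
  expect_equal(sum(net$nodes$role == "TF"), 5)
  expect_equal(sum(net$nodes$role == "gene"), 5)
})
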