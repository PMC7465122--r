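# coexffl

Network inference for paired tumour/normal transcriptome cohorts, built
around the analysis strategy used in non-small-cell lung cancer (NSCLC)
biomarker studies: find genes that are reproducibly deregulated across
cohorts, organise them into co-expression modules, pull out the densest
protein-interaction cluster among the representative module genes, call
hub genes by enrichment-term intersection, wire the hubs into a
miRNA–TF–gene feed-forward-loop (FFL) network, and ask whether any of it
predicts survival. Every stage is file-based and runs offline; a
synthetic-data generator with planted ground truth makes the whole chain
testable without downloading anything.

Intended users are computational biologists who want a scripted,
reproducible version of what is usually a chain of web tools (GEO +
STRING + Cytoscape/MCODE + Enrichr + miRWalk/ChEA + KM-plotter).

## What it computes

**Meta-differential expression.** Per dataset, a classic paired t-test on
tumour-minus-normal differences per gene; evidence combined across *k*
datasets with Fisher's method,

    X = -2 * sum_i ln(p_i),   p_comb = P(chi2_2k >= X),

then Benjamini–Hochberg control. Genes with BH-p < 1e-4 and |log2FC| > 1.5
(strict) are meta-DEGs, classified up or down by the sign of the pooled
log2 fold change.

**Weighted co-expression network.** Unsigned similarity s_ij = |cor(x_i,
x_j)| raised to a soft power β chosen by the scale-free topology
criterion (signed R² ≥ 0.80 over 1..20); topological overlap

    w_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij),  l_ij = sum_u a_iu a_uj;

average-linkage clustering of 1−TOM with an adaptive-height branch cut
(minimum module size 30), eigengene-based module merging at MEdiss < 0.2,
intramodular connectivity (k.in, ω.in, kTotal, kOut, kDiff), module
membership MM = cor(x_i, ME), a |kME| < 0.7 grey reassignment, and
representative genes at MM > 0.9.

**Dense interaction clusters.** A from-scratch MCODE implementation
(vertex weight = core density × highest core order of the closed
neighbourhood; seed-and-expand at node score cutoff 0.2; haircut;
clusters scored density × n) on the STRING-style edge table thresholded
at combined score > 0.9.

**Hub genes.** Hypergeometric enrichment of the top cluster against GMT
libraries (BH within library, α = 0.001); the hub set is the intersection
of the query overlaps of *all* significant terms.

**FFL assembly.** Regulatory edge tables filtered at miRNA target score
> 0.95 with 3'UTR binding and TF p < 0.001; a two-tier screen (literature
whitelist, then human–mouse conservation of miRNAs); motif extraction of
closed miRNA→TF→gene loops merged per (miRNA, gene) pair, ranked by
summed node degree.

**Survival.** Median-split cohorts, Kaplan–Meier curves with median
survival, the log-rank test, and the Mantel–Haenszel hazard ratio with a
95% CI.

## Worked example

```r
library(coexffl)
cfg    <- sim_config(seed = 7)                      # planted ground truth
bundle <- simulate_bundle(cfg, "sim_inputs")        # writes all input files
summary <- run_pipeline(pipeline_config(bundle_paths("sim_inputs"), seed = 7),
                        "run_out")

str(summary$meta_deg)
#> List of 4
#>  $ n_genes_tested: int 1000
#>  $ n_meta_degs   : int 200
#>  $ n_up          : int 135
#>  $ n_down        : int 65

summary$enrichment_hub$hub_genes
#> [1] "G0298" "G0415" "G0467" "G0476" "G0615"

str(summary$ffl$motif)
#> List of 4
#>  $ mirna: chr "hsa-miR-501-5p"
#>  $ tfs  : chr [1:2] "TFX1" "TFX2"
#>  $ gene : chr "G0298"
#>  $ order: int 10

round(unlist(summary$survival[[1]]), 3)
#>          hr      ci_low     ci_high   logrank_p  median_low median_high
#>       2.276       1.621       3.195       0.000      41.821      18.106
```

The 200 meta-DEGs are exactly the planted DE genes; the five hub genes
are the planted interaction clique; the extracted motif is the planted
composite loop (one miRNA repressing two TFs and a hub gene the TFs also
regulate); and the high-expression cohort of the first hub gene shows the
planted hazard ratio of about 2 with a much shorter median survival.
A single desk check ties the cluster scoring to a published value:

```r
cluster_score(24, 256)
#> [1] 22.261
```

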