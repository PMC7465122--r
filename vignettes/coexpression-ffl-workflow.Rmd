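---
title: "From paired cohorts to feed-forward loops: the coexffl workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From paired cohorts to feed-forward loops: the coexffl workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexffl)
```

## The analysis in one paragraph

Given two or more cohorts of paired tumour/normal expression profiles,
the workflow asks: which genes are reproducibly deregulated, how do they
organise into co-expressed modules, which tightly interacting subset of
the strongly module-associated genes forms a functional unit, what do the
enrichment terms agree those genes are, which miRNAs and transcription
factors plausibly wire them into feed-forward loops, and does any of this
carry prognostic signal? Each question is one pipeline stage with a small
number of thresholds; the defaults reproduce the settings of the
reference NSCLC analysis the package is modelled on.

## Stage models and their assumptions

### Meta-differential expression

Each dataset contributes a classic paired t statistic per gene,
`t = mean(d) / (sd(d)/sqrt(n))` on the per-subject tumour-minus-normal
differences. The per-dataset p-values are combined with Fisher's method
(`X = -2 * sum(ln p)`, chi-squared on 2k df) and BH-adjusted. This
assumes the datasets are independent and that each gene's differences are
approximately normal; it does not moderate variances across genes (no
empirical-Bayes shrinkage), which is deliberate — the reference procedure
uses the plain paired t.

Numerical choices worth knowing:

* p-values of exactly 0 (possible only by underflow) are clamped to the
  smallest positive double before the logarithm so `X` stays finite;
* genes with zero difference variance get `NA` p-values and are excluded
  from the BH adjustment (the number of tests shrinks accordingly) rather
  than silently treated as significant;
* matrices whose maximum exceeds 30 are assumed to be on the raw
  intensity scale and are `log2(x+1)`-transformed with a warning, since
  series-matrix deposits are usually but not always logged;
* the pooled log2FC is the mean over all tumour columns minus the mean
  over all normal columns, pooled across datasets; per-dataset fold
  changes are emitted alongside for audit. A per-dataset average would
  weight small cohorts more heavily; pooling was chosen for simplicity
  and transparency.

All classification thresholds are strict inequalities (BH-p < 1e-4,
|log2FC| > 1.5), so boundary values are *not* significant.

### Weighted co-expression network

The network is unsigned: `s_ij = |cor|`, so strongly anti-correlated
genes are treated as connected — consistent with modules defined by
shared regulation regardless of direction. The soft power is the smallest
β in 1..20 whose connectivity distribution fits a power law with signed
R² ≥ 0.80. The fit bins connectivities into 10 equal-count bins,
estimates an empirical density per bin and regresses log-density on
log-mean-connectivity; the sign guard (R² negated for increasing fits)
prevents rewarding anti-scale-free shapes. If no candidate reaches the
target the argmax is used with a warning — on small latent-factor
networks (a few hundred genes, a handful of modules) the scale-free
criterion is often unattainable, and the chosen argmax power behaves
sensibly downstream because only the ranking of adjacencies matters for
module detection.

The topological overlap is the standard unsigned form
`w_ij = (l_ij + a_ij)/(min(k_i, k_j) + 1 - a_ij)`; the dissimilarity
1−TOM feeds average-linkage clustering.

**Branch cutting.** Module detection cuts the dendrogram at the height
that maximises the number of branches of at least `min_module_size`
genes, taking the largest such height so branches are as complete as
possible; smaller branches become "grey" (unassigned). This is a
deliberately simple, fully deterministic alternative to the dynamic
hybrid tree cut: it has one parameter, is easy to reason about, and on
block-structured dissimilarities it provably recovers the blocks. What it
gives up is the ability to resolve nested modules that form at very
different heights on the same branch; for the module scales this package
targets (tens to a couple of hundred genes per module) the planted-module
recovery contract (adjusted Rand ≥ 0.8 on the standard fixture) is the
operative guarantee, and it is exercised in the test suite.

Eigengenes are first principal components of the row-standardised module
submatrix, unit-variance, sign-oriented to correlate positively with the
module's mean standardised profile (so "high eigengene" means "high
average expression"). Modules merge greedily while the smallest
eigengene dissimilarity is below 0.2 (correlation above 0.8), recomputing
eigengenes after every merge; the larger module's label survives, with a
lexicographic tie-break. The `|kME| < 0.7` grey reassignment is applied
once, after merging — applying it earlier would change which modules
exist at merge time, and the reference procedure does not say when it was
applied, so the least intrusive point was chosen.

Connectivity sums exclude the diagonal (a gene is not its own
neighbour). Representative genes require MM strictly above 0.9.

### Dense-cluster detection

MCODE is implemented from its published description: the weight of a
vertex is the density of the highest k-core of its closed neighbourhood
times that core's order; seeds are taken in decreasing weight order
(name-ordered at ties); expansion admits neighbours with weight ≥
seed weight × (1 − 0.2); vertices never join two clusters; the haircut
iteratively removes vertices with fewer than two intra-cluster
connections (equivalently, keeps the cluster's 2-core); clusters need at
least 3 nodes and a 2-core. The "fluff" stage is omitted: the
configuration this package reproduces runs with haircut on and fluff
off, so the fluff path would be dead code. Ranking is by score
(density × n), then node count, then lexicographically smallest member —
the plugin leaves ties unspecified, so they are pinned down here for
determinism. Scores are reported to three decimals, which is how the
published top-cluster score of 22.261 for a 24-node, 256-edge cluster
arises from `2*256/(24*23) * 24`.

Edge tables are auto-normalised from the STRING 0–1000 scale when any
score exceeds 1, and the confidence threshold (default 0.9) is strict.

### Enrichment and hub calling

Hypergeometric upper-tail p-values with BH correction *within* each
library, mirroring per-library ranking semantics of enrichment web
services; a global correction across libraries would be more conservative
and is not what the reference decision rule (BH-p < 0.001 per library)
implies. The default background is the union of all term genes in the
library. This choice matters: a smaller, analysis-specific universe
inflates significance of broad terms, a genome-wide universe deflates it.
Supply `universe=` explicitly when a better background is known.

The hub set intersects the *query overlaps* of all significant terms
(not the full term gene sets). When every significant term contains the
whole query the two readings coincide; the overlap reading is adopted
because it can only be more specific.

### Feed-forward loops

Filters are strict (`score > 0.95` and 3'UTR binding for miRNA edges;
`p < 0.001` for TF–gene edges) and commute with the two-tier screen, a
property the test suite checks. Name matching across species strips
`hsa-`/`mmu-` prefixes and lower-cases. The mouse-conservation
requirement applies to both miRNA–gene and miRNA–TF edges by default
(`conserve_targets = "all"`); restrict it to gene targets with
`"genes"` if the conservation evidence only covers 3'UTR target sites.
TFs pass on literature (tier-1) membership alone — the conservation tier
is defined for miRNAs.

"Highest-order motif" is read as the composite instance (one miRNA, one
gene, all TFs closing a loop between them) with the largest summed degree
of its constituent nodes in the merged network; an alternative reading
(largest single-node degree) would favour promiscuous regulators over
coherent loops. Ties prefer more TFs, then lexicographic names.

`table2_tables()` deserves a note: the published network summary prints
only marginal counts (19/25/22 edges over 11 miRNAs, 5 genes, 5 TFs).
The function returns a deterministic *synthetic* edge set honouring every
printed marginal — it is bookkeeping scaffolding for tests and examples,
not a reconstruction of the unpublished individual pairs, and the
unnamed regulators carry obviously synthetic identifiers.

### Survival

Median split with ties to the low cohort (web tools do not document
their tie rule; this one is stated). Kaplan–Meier with deaths processed
before censorings at ties; the median is the smallest time with
S(t) ≤ 0.5 and is reported as undefined when the curve never crosses it.
The hazard ratio is Mantel–Haenszel, `(O2/E2)/(O1/E1)` with
`var(log HR) = 1/E1 + 1/E2`, matching what univariate median-split
survival tools report; a Cox fit would add a dependency and can diverge
from MH in small samples — if you need Cox, `survival::coxph` on the
same split is one line. Published hazard ratios from database-backed
tools are treated as documentation examples only; they derive from
cohorts this package does not ship.

## The synthetic generator: what it emulates, and what it does not

The generator plants every structure the pipeline is supposed to find:

* **Paired cohorts** (default two, 50 pairs each) on the log2 scale with
  gene baselines Uniform(4, 12) shared across datasets plus a per-dataset
  per-gene offset (SD 0.3) standing in for cohort effects. Expression is
  simulated directly on the log2 scale because every downstream statistic
  operates there; no probe-level or intensity-scale model is attempted.
* **Modules** as single-latent-factor blocks: gene = loading × factor +
  noise, with loading 0.9 and noise SD 0.5, so intra-module correlation
  is about 0.76 before the DE shift. Ten **core genes** per module carry
  loading 0.98 with complementary noise (variance 1 − 0.98²), giving them
  eigengene correlation ≈ 0.98 — these are the genes an MM > 0.9 screen
  is meant to single out, and the planted interaction clique is drawn
  from module 1's cores.
* **DE genes** (default 20% of 1000) are the module genes first — odd
  modules shifted up, even modules down by 2.0 log2 units in tumour
  columns — plus background genes with alternating signs. Making the
  module genes the DE genes mirrors the real pipeline, where the
  co-expression network is built on the meta-DEGs.
* **The interaction graph**: the clique fully connected with scores in
  (0.95, 1), background Erdős–Rényi (p = 0.05) with scores mixed across
  the 0.9 threshold.
* **Gene-set libraries**: two planted terms per library containing the
  whole clique, the rest random draws.
* **Regulatory tables**: the planted composite FFL passes every filter
  and screen; each decoy fails exactly one barrier (score, region, TF p,
  tier-1, mouse), cycling deterministically, so any over-permissive
  filter shows up as a decoy leaking through.
* **Survival**: exponential event times, baseline mean 60 months, hazard
  multiplied by exp(hazard_coeff × z). By default z is the above-median
  indicator of a shared latent severity that also drives prognostic-gene
  expression (separation 2.0, noise 0.4, misclassification under a
  median split < 1%), so the median-split Mantel–Haenszel HR targets
  exp(hazard_coeff) directly — this is the covariate the analysis stage
  actually dichotomises. A literal continuous-covariate mode
  (`effect = "linear"`) is provided; under it the median-split HR is an
  attenuated function of the coefficient, not exp(coeff). Censoring is
  an independent coin flip at `censor_rate` with uniform back-dating.

What the generator does **not** emulate: probe-level artefacts,
batch effects beyond per-dataset baselines, correlated censoring,
signed co-expression structure, overlapping modules, or realistic
miRNA/TF target-score distributions. Passing tests therefore certify the
*machinery* — that each stage finds what is planted under its stated
model — not performance on real microarray data, where annotation
versions, outlier arrays and confounded batches dominate.

One global seed fans out to per-generator substreams through fixed
offsets, so every generator is individually reproducible and
byte-identical under a repeated seed.

## Problem sizes and runtime

The default fixture uses 1000 genes, 2 × 50 pairs, three modules of
80/60/50 genes, a 5-clique, 20-term libraries and 200 survival subjects;
the full pipeline runs in roughly two seconds. Calibration checks in the
test suite use 100 null replicates of a 200-gene two-cohort design (the
meta-DEG count at the reference thresholds is 0 in ≥ 95% of them) and
500 null survival replicates (log-rank size 5% ± 2%); oracle-equivalence
checks run the brute-force reimplementations on 100 random instances per
operation at sizes ≤ 12 nodes / 50 p-values / 20 subjects. These sizes
were chosen as the smallest at which the respective statistics are
well-behaved.

## Known limitations

* The adaptive-height cut cannot separate nested modules on one branch;
  strongly unbalanced module sizes with overlapping height ranges may
  merge.
* The scale-free criterion rarely reaches R² 0.80 on small simulated
  networks; the argmax fallback is flagged (`reached_target = FALSE`)
  rather than hidden.
* Enrichment p-values depend on the background choice; defaults are
  library-union and are stated prominently rather than silently assumed.
* Exact replication of published module memberships from deposited
  cohorts is not promised: probe-collapse order, annotation versions and
  unstated tree-cut parameters all perturb counts. The pipeline reports
  every intermediate count in `summary.json` so discrepancies are
  attributable stage by stage.
* The Mantel–Haenszel HR differs from a Cox estimate in small samples or
  under heavy censoring.
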