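---
title: "Methods: recovery stratification of single-cell expression across dietary conditions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recovery stratification of single-cell expression across dietary conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screcover)
```

# The question and the data model

Obesity remodels the immune compartment of visceral adipose tissue:
macrophage subpopulations expand, regulatory populations shrink, and
thousands of genes change expression within each leukocyte subtype. When
obese animals are then calorically restricted, two distinct things can
"recover": the *composition* of the leukocyte pool, and the *expression
programs* within each subpopulation. `screcover` measures both.

The package operates downstream of alignment, UMI counting, dataset
integration, and clustering: its inputs are a sparse genes × cells UMI
count matrix, a per-cell table giving each cell's condition (`lean`,
`obese`, or `CR`) and cluster label, and optionally a GMT gene-set
collection. Cluster labels are consumed as given; no clustering,
embedding, or cell-type annotation is performed here.

# Cell quality control

Three rules, in order:

1. **Degenerate cells.** Cells with zero total UMI fail outright.
2. **High outliers, per condition.** A cell fails if its mitochondrial
   UMI fraction (genes with the `mt-` prefix) or its total UMI count
   exceeds `median + k · 1.4826 · MAD` of that metric, computed among the
   cells of its *own condition* — each 10x run is filtered on its own
   distribution, since depth and viability differ between runs. The rule
   is one-sided (`k = 3` by default): only high mitochondrial content
   (apoptosis) and high depth (doublets) are pathological here; low-end
   filtering is assumed to have happened at the cell-calling stage. With
   zero spread (MAD = 0 and all values equal) nothing fails.
3. **Non-leukocyte clusters.** A cluster is dropped — all its cells fail
   QC — when fewer than 5% of its cells have a nonzero count of the CD45
   gene (*Ptprc*), the pan-hematopoietic marker. The comparison is a
   strict less-than, so a cluster exactly at the threshold is retained.
   The 5% default operationalizes "does not show expression of CD45";
   any serious leukocyte cluster detects *Ptprc* in far more cells, and
   ambient contamination keeps truly negative clusters near zero.

Normalization is the standard depth/log transform
`ln(1 + s · count / depth)` with `s = 10⁴`. Zeros map to zero, so
sparsity is preserved, and scaling a cell's counts by any constant leaves
its normalized profile unchanged.

# Differential expression

Within each cluster, each pair of conditions is compared gene by gene
with the two-sided Wilcoxon rank-sum test on normalized expression. No
gene is pre-filtered by effect size or detection rate: fold changes are
wanted even in clusters where a gene cannot reach significance. The exact
null distribution is used when the smaller group has ≤ 8 observations and
there are no ties; otherwise the normal approximation with midranks,
tie-corrected variance and continuity correction. P-values are BH-adjusted
*within each cluster × contrast family*, mirroring how per-cluster DE
lists are reported, rather than globally.

The log fold change is `ln((mean_a + 1) / (mean_b + 1))`, where each mean
is the group average of the *de-logged* normalized expression
(`expm1` of the log-normalized value, i.e. counts per 10⁴ UMI) and the
pseudocount is 1. This is stated explicitly because the downstream
fold-change heatmaps and the 1.5-fold rule depend on it.

A contrast needs at least `min_cells = 3` cells in each group; below
that, the whole (cluster, contrast) family is *NotAssessed* — the normal
state of affairs for a cluster absent in one condition — rather than a
grid of `NA` p-values.

**Markers.** A gene is a marker of a cluster when it is detected in at
least 25% of the cluster's cells, higher there than in all other cells
(positive logFC in the one-vs-rest contrast), and BH-significant at
α = 0.05. Marker definitions in the field often leave the significance
requirement implicit; it is imposed explicitly here, since a fold-change
ranking without an error bar is not a defensible marker list.

# Recovery stratification

For each selected gene and assessable cluster, let `L`, `O`, `C` be the
de-logged mean normalized expression in lean, obese, and CR cells. With
relative difference `rd(C, X) = |C − X| / max(X, ε)`:

1. if `C` is **not** between `L` and `O`, and `rd(C, L) > τ` and
   `rd(C, O) > τ` → **Different**;
2. else if `|C − L| < |C − O|` → **Recovered**;
3. else → **NotRecovered** (including exact ties).

Defaults: `τ = 0.10`, `ε = 10⁻⁶`.

Three genuinely open choices, and how they were fixed:

- **Scale.** The 10%-difference rule is applied on de-logged per-cluster
  condition means — the same scale as the fold changes — so "10%
  different" reads directly as a 10% relative change in expression. A
  log-scale or absolute-difference reading would make τ depend on
  expression magnitude in ways that are hard to state.
- **Precedence.** A non-intermediate `C` far from both references is
  always strictly closer to one of them; Different must therefore take
  precedence over rules 2–3 or the class would be empty by construction.
- **Ties.** `|C − L| = |C − O|` is called NotRecovered: conservative
  against claiming recovery.

The classifier is scale-invariant (`classify_gene(sL, sO, sC)` is
constant in `s > 0` above the ε floor), exhaustive and exclusive over
assessed pairs, and is verified in the tests against an independent
re-implementation on the full integer grid `(L, O, C) ∈ {0..30}³`.

Gene selection for stratification: any gene with BH-adjusted p < α in at
least one pairwise contrast in at least one cluster. Per-cluster category
proportions are reported with two denominators: genes DE in
obese-vs-lean *within that cluster* (the default — "of the genes obesity
changed here, how many recovered?") or all selected genes; both are kept
because the phrase "genes differentially expressed in obese tissue" is
ambiguous between the two. Cross-cluster sharing is summarized per
category as the histogram, over genes, of the number of clusters carrying
that category.

# Coordination and composition

**Coordinated changes.** Genes with `|logFC| ≥ ln(1.5)` (inclusive) *and*
BH significance in at least one cluster of the obese-vs-lean contrast
form the rows of a genes × clusters logFC matrix; entries are
unthresholded so that sub-threshold but concordant changes remain
visible. Requiring significance in the triggering cluster keeps
noise-only large folds in tiny clusters out of the matrix. Rows are
clustered agglomeratively (complete linkage, Euclidean metric by default:
deterministic and checkable against a textbook implementation; both are
configurable). Entries from NotAssessed clusters are imputed as 0 — "no
evidence of change" — and flagged. Under the correlation metric, constant
rows have no defined distance and are isolated in singleton clusters with
a warning.

**Composition.** Cluster proportions are computed per condition over
QC-passing cells. Each cluster's triple `(p_lean, p_obese, p_CR)` is then
classified with the *same* recovery rule — reusing the gene-level
classifier keeps the definition testable and symmetric — with one
addition: clusters whose obese proportion is within τ (relative) of lean
were never shifted by obesity and are called **Unchanged**; otherwise
Recovered ↦ RevertedToLean, NotRecovered ↦ RemainedShifted, Different ↦
UniqueToCR. Any numeric rule here is a reconstruction of a verbal
grouping, and this one is deliberately the simplest that reproduces the
motifs of interest (e.g. a cluster absent in lean that expands well past
its obese share after CR is UniqueToCR).

# Gene-set enrichment

Over-representation only: for a target gene list against a background
universe (all genes with detectable expression), each set is first
intersected with the universe, then scored with the upper-tail
hypergeometric probability `P(X ≥ k)` for `X ~ Hypergeom(N, K, n)`;
BH across sets. This is the "target vs background" mode of the usual
GO/KEGG tools; threshold-optimizing variants (mHG) and DAG-aware
propagation are out of scope. No GO/KEGG snapshot is bundled — term
databases are versioned, and a frozen copy would be silently stale — so
collections are user-supplied GMT files.

# The synthetic-data generator

`generate_dataset()` draws counts `NB(mean = sf_c · m_{g,k,j}, size = φ)`
for gene g, cluster k, condition j, with per-cell size factors
`sf ~ Lognormal(σ = 0.3)` normalized to mean 1. Defaults mirror the
three-condition mouse experiment in scale: 2268 / 5232 / 2458 cells in
lean / obese / CR, 15 clusters, ~2000 genes. The default cluster
proportions encode the two composition motifs the pipeline must detect —
cluster 1 at (0.16, 0.38, 0.17) of cells (expands in obesity, reverts
after CR) and the last cluster at (0, 0.07, 0.30) (absent in lean,
CR-unique) — with the remainder spread evenly.

Gene roles: a constitutive *Ptprc*; mitochondrial (`mt-`) genes at a
uniformly high baseline (1.5–2.5× `baseline_mean`), as real mitochondrial
transcripts are; per-cluster marker genes elevated 4-fold in their own
cluster; planted Recovered / NotRecovered / Different genes (100 each by
default) whose condition means are `C* = L*`, `C* = O*`, and a
non-intermediate placement beyond the classifier threshold respectively,
with `O* = L* · 2` (or `/2`); everything else is null. Planted triples
are re-checked against `classify_gene()` at construction, so category
soundness holds by definition.

**Mass balance, the one subtle design constraint.** Depth normalization
divides by the cell's total count, so anything that changes a
*condition's total expression mass* reappears, with opposite sign, in
every other gene of that condition. Early versions of the generator drew
planted effect directions at random and placed all Different genes above
both references; the resulting few-percent CR mass excess biased every
null and Recovered gene downward in CR by ~7% — most of the way to the
10% Different threshold — and manufactured real compositional DE in
"null" genes. The generator therefore plants effects in up/down pairs
with swapped masses (the pair's lean and obese totals are identical),
and splits Different genes between above-both (`max·d`) and below-both
(`min/d`) placements in the ratio that cancels their net CR excess
(below-both is only used when `1 − 1/d > τ`, or the placement would not
be legally "Different"). This is not cosmetic: it is what makes "null
gene" mean null after normalization.

Remaining defaults, chosen once from a power analysis of the classifier
at the test scale (~200 cells per cluster-condition) and not revisited:
`baseline_mean = 8` UMI per cell per gene (the generator emulates the
~2000 *variable* genes of an experiment, not a full transcriptome, so
moderate means are the realistic regime), NB size `φ = 10`
(within-cluster biological noise beyond the lognormal depth variation),
`divergence_fold = 1.5` (a Different gene 50% beyond the nearer
reference; comfortably past τ = 0.10 at this noise level),
`effect_fold = 2`.

**Outliers.** High-mitochondrial cells are created by inflating `mt-`
counts until the mitochondrial fraction reaches
`max(0.25, 6 × cohort median)` — far beyond any MAD cutoff, as true
apoptotic cells are. Doublets add the full count vector of a
same-condition partner to a host cell; hosts and partners are drawn from
the deepest third of their condition's UMI distribution. The latter is a
deliberate restriction: under a lognormal(σ = 0.3) depth law the sum of
two *shallow* cells is statistically indistinguishable from one deep
singlet, so unrestricted doublets would make the planted truth partially
unlearnable by any depth-based rule — the generator plants the detectable
regime that UMI-outlier QC is designed for. Planting re-seeds from
`seed + 1`, so it is reproducible standalone.

**What the generator does not emulate** — and therefore what passing
tests do not certify about real data: ambient RNA, batch and chemistry
effects, integration (CCA) artifacts, clustering errors (labels are
taken as true), UMI saturation, gene–gene correlation beyond cluster
structure, and dropout beyond what the NB itself produces. Parameter
recovery on this generator validates the *inference machinery*, not any
particular biological claim.

# Numerical choices and degenerate inputs

- Exact vs approximate Wilcoxon switches at min(n) ≤ 8 with no ties;
  zero rank variance (all values tied) returns p = 1.
- BH is applied per family; adjusted values are capped at 1 and never
  below the raw p.
- `ε = 10⁻⁶` floors the relative-difference denominators so silent genes
  cannot divide by zero; a planted mean of exactly 0 against a positive
  CR mean is thus always "more than τ different".
- `min_cells = 3` defines assessability everywhere (contrasts, condition
  means, marker clusters).
- Hierarchical clustering imputes missing entries as 0 and reports the
  imputation mask; cutting at `k` larger than the usable rows silently
  reduces `k`.
- MatrixMarket files whose declared nonzero count disagrees with their
  entry lines are rejected before parsing (the underlying reader would
  silently accept truncation); sidecar length mismatches are rejected
  naming the offending file.
- All randomness flows from the single config seed (`set.seed(seed)` in
  generation, `seed + 1` in outlier planting); identical configs are
  byte-identical.

# Problem sizes used in validation

The shipped tests run the full pipeline on a reduced cohort — 5 clusters
(one absent in lean), 800/1000/1000 cells (~200 per cluster-condition),
2000 genes, 300 planted effects — where the classifier's expected
per-pair accuracy is ≈ 97–99%, against an acceptance bar of 90%. QC
specificity is estimated by pooling ten such cohorts, because the true
clean-cell failure rate under these conditions sits near 1.9% (the
one-sided 3-MAD cutoff lands at ≈ 2.1σ of a lognormal(0.3) depth law)
against a 2% bar, and a single-cohort estimate of a rate that close to
its bound is underpowered. Enumeration oracles (rank-sum, BH,
hypergeometric, complete linkage, the classifier grid) cover the small-n
regime exhaustively.

# Known limitations

- The Wilcoxon test treats cells as exchangeable replicates; with one
  animal pool per condition, p-values quantify cell-to-cell variation,
  not biological replication across animals — the convention of
  cell-level scRNA-seq DE workflows, but worth stating.
- The 10% rule's scale (de-logged means) and the composition rule are
  documented reconstructions of verbal definitions; alternative readings
  would shift category boundaries.
- BH within families controls FDR per cluster × contrast, not globally
  across the whole experiment.
- The enrichment module ignores gene-set redundancy and GO structure.
- No pseudobulk or mixed-model DE, no covariate adjustment, no ambient
  correction, no doublet detection beyond the UMI rule.
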