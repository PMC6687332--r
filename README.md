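# screcover

Does caloric restriction return the gene expression of adipose-tissue
leukocytes to the lean state, or do the cells remain transcriptionally
"obese"? `screcover` implements the analysis needed to answer that question
from three-condition single-cell RNA-seq data — one cohort of cells from
lean animals, one from obese, and one from obese animals after caloric
restriction (CR) — with cells already assigned to clusters (cell
subpopulations). It is aimed at computational biologists analyzing
multi-condition droplet scRNA-seq experiments who need the full chain from
raw UMI counts to per-gene "recovery" calls in tested, scriptable form.

## What it computes

**Recovery stratification (the core).** For each gene and cluster, let
`L`, `O`, `C` be the mean de-logged normalized expression in the lean,
obese, and CR cells of that cluster. Each gene significantly
differentially expressed between any pair of conditions (two-sided
Wilcoxon rank-sum on normalized expression, Benjamini–Hochberg FDR within
each cluster × contrast family, α = 0.05) is classified as:

- **Different** — `C` lies outside `[min(L,O), max(L,O)]` *and*
  `|C−X| / max(X, ε) > τ` for both `X = L` and `X = O` (default
  `τ = 0.10`: more than 10% away from both);
- **Recovered** — otherwise, `C` is strictly closer to `L`;
- **NotRecovered** — otherwise (closer to `O`, ties conservatively not
  recovered).

Clusters missing a condition (e.g. a subpopulation absent in lean
animals) are reported as **NotAssessed**.

**Around it:**

- per-cell QC: one-sided outlier removal at
  `median + 3 × 1.4826 × MAD` per condition on mitochondrial fraction
  (apoptotic cells) and total UMI (doublets), plus exclusion of clusters
  that do not detectably express CD45 (*Ptprc*), i.e. are not leukocytes;
- `ln(1 + 10^4 · count / depth)` normalization;
- per-cluster pairwise differential expression and one-vs-rest marker
  detection (expressed in ≥ 25% of the cluster's cells, higher there than
  elsewhere, BH-significant);
- coordinated-change analysis: genes changing ≥ 1.5-fold in obesity in any
  cluster, their log fold-change profile across all clusters, and
  complete-linkage hierarchical clustering of those profiles;
- cluster-composition shifts across conditions, classified with the same
  rule (RevertedToLean / RemainedShifted / UniqueToCR / Unchanged);
- hypergeometric (upper-tail) gene-set enrichment of each recovery
  category against a GMT collection, target vs background.

**Synthetic data with planted truth.** Because every stage needs to be
testable without access to any particular animal dataset, the package
ships a negative-binomial simulator (`sim_config()`, `simulate_dataset()`)
that plants known Recovered/NotRecovered/Different genes, cluster markers,
high-mitochondrial cells, doublets, and an absent-in-lean cluster — and
records all of it in a truth table for parameter-recovery checks.

## Worked example

```r
library(screcover)

cfg <- sim_config(n_genes = 600, n_clusters = 5,
                  cells_per_condition = c(lean = 500, obese = 600, CR = 600),
                  n_planted_per_category = c(Recovered = 30, NotRecovered = 30,
                                             Different = 30),
                  n_outlier_cells = 10, n_doublets = 5, seed = 2024)
sim <- simulate_dataset(cfg)
res <- run_pipeline(sim$counts, sim$cells, outdir = "vat_results")

head(res$recovery[res$recovery$category != "NotAssessed", ], 3)
#>        gene cluster        L        O        C     category
#> 1 Gene00021      C1 71.91161 64.89374 69.20412    Recovered
#> 2 Gene00032      C1 13.19532 13.78399 14.47542 NotRecovered
#> 3 Gene00040      C1 19.41419 20.87993 20.28207 NotRecovered

res$proportions
#>   cluster n_genes Recovered NotRecovered Different
#> 1      C1      91 0.2967033    0.3296703 0.3736264
#> 2      C2      95 0.3052632    0.3578947 0.3368421
#> 3      C3      96 0.3229167    0.3020833 0.3750000
#> 4      C4      93 0.3548387    0.3118280 0.3333333

res$composition_recovery
#>   cluster    p_lean    p_obese      p_CR        category
#> 1      C1 0.1567010 0.39619377 0.1925043  RevertedToLean
#> 2      C2 0.2639175 0.19723183 0.1584327      UniqueToCR
#> 3      C3 0.3237113 0.18858131 0.1805792 RemainedShifted
#> 4      C4 0.2556701 0.16262976 0.1788756 RemainedShifted
#> 5      C5 0.0000000 0.05536332 0.2896082      UniqueToCR
```

Reading the output: in cluster C1, `Gene00021` was pulled down by obesity
(`O < L`) and its CR mean sits back near the lean level — Recovered. The
`proportions` table says that of the genes obesity changed in each
cluster, roughly 30–35% recovered after two weeks of CR while the rest
stayed obese-like or moved somewhere new. The composition table shows the
planted motifs: C1 expanded from ~16% to ~40% of cells in obesity and
reverted after CR; C5 is absent in lean animals (`p_lean` exactly 0) and
grows to ~29% of CR cells, a CR-unique subpopulation — so its genes are
NotAssessed for recovery (no lean reference exists). `run_pipeline()` also
wrote every table (QC'd cell table, DE results, markers, recovery,
fold-change matrix with gene modules, composition, enrichment when a GMT
is supplied) as TSV files under `vat_results/`.

The same stages are available from a shell via the bundled CLI:

```sh
Rscript inst/cli/screcover.R simulate --out data --seed 1
Rscript inst/cli/screcover.R qc --counts data --cells data/cells.tsv --out out
Rscript inst/cli/screcover.R de --counts data --cells out/cells_qc.tsv --out out
# ... recover, coordination, composition, enrich; see --help per subcommand
```

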