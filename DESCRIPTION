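Package: screcover
Title: Recovery Stratification of Single-Cell Gene Expression Across
    Dietary Conditions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for three-condition (lean, obese, caloric
    restriction) single-cell RNA-seq leukocyte data: per-cell quality
    control with robust outlier filtering, CD45-based exclusion of
    non-leukocyte clusters, depth normalization, per-cluster pairwise
    Wilcoxon differential expression with Benjamini-Hochberg correction,
    cluster marker detection, stratification of differentially expressed
    genes into Recovered / NotRecovered / Different states after caloric
    restriction, coordinated fold-change analysis across cell types,
    cluster-composition shift analysis, and hypergeometric gene-set
    enrichment. Includes a negative-binomial synthetic-data generator
    that plants known ground truth (effect categories, outlier cells,
    doublets, an absent-in-lean cluster) so every stage is testable
    without access to external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
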