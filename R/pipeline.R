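#' Run the full three-condition analysis pipeline
#'
#' QC (per-cell metrics, per-condition outlier filtering, CD45 cluster
#' exclusion), depth normalization, per-cluster pairwise differential
#' expression, marker detection, recovery stratification with per-cluster
#' proportions and cross-cluster overlap, coordinated fold-change analysis
#' with hierarchical gene clustering, cluster-composition analysis, and
#' (when gene sets are supplied) hypergeometric enrichment per recovery
#' category. All stage outputs are written as TSV files to `outdir`.
#'
#' @param counts genes x cells count matrix.
#' @param cells cell table (barcode, condition, cluster).
#' @param outdir output directory; created if missing. NULL skips writing.
#' @param gene_sets optional named list of gene sets (see [read_gmt()]).
#' @param qc a [qc_params()].
#' @param marker a [marker_params()].
#' @param classifier a [classifier_params()].
#' @param fold_threshold fold cutoff of the coordinated-change analysis.
#' @param mito_prefix mitochondrial gene prefix.
#' @param min_cells minimum group size for contrasts and condition means.
#' @param n_modules flat gene-module count cut from the fold-change
#'   dendrogram.
#' @return (invisibly) a list with every intermediate result: cells, norm,
#'   de, markers, genes, recovery, proportions, overlap, logfc, modules,
#'   composition, composition_recovery, enrichment.
#' @export
run_pipeline <- function(counts, cells, outdir = NULL, gene_sets = NULL,
                         qc = qc_params(), marker = marker_params(),
                         classifier = classifier_params(),
                         fold_threshold = 1.5, mito_prefix = "mt-",
                         min_cells = 3L, n_modules = 4L) {
  validate_counts(counts)
  cells <- compute_cell_qc(counts, cells, mito_prefix)
  cells <- filter_cells(cells, qc)
  excl <- exclude_nonleukocyte_clusters(counts, cells, qc)
  cells <- excl$cells

  keep <- cells$barcode[cells$qc_pass]
  norm <- normalize_counts(counts[, keep, drop = FALSE], qc)

  de <- run_de(norm, cells, min_cells = min_cells, params = qc)
  markers <- find_markers(norm, cells, marker, qc)

  genes <- select_recovery_genes(de, alpha = classifier$alpha)
  rtab <- build_recovery_table(norm, cells, genes, classifier, min_cells)
  props <- recovery_proportions(rtab, "obese_de_only", de = de,
                                alpha = classifier$alpha)
  overlap <- cluster_overlap_distribution(rtab)

  lfc <- coordinated_logfc_matrix(de, "obese vs lean", fold_threshold,
                                  classifier$alpha)
  modules <- if (nrow(lfc) >= 2L)
    hierarchical_cluster_genes(lfc, k = n_modules) else NULL

  comp <- cluster_composition(cells)
  comp_rec <- composition_recovery(comp, classifier)

  enr <- NULL
  if (!is.null(gene_sets) && length(gene_sets)) {
    background <- rownames(counts)[
      Matrix::rowSums(counts[, keep, drop = FALSE] > 0) > 0]
    enr <- enrich_by_category(rtab, background, gene_sets)
  }

  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    tsv <- function(x, f) write.table(x, file.path(outdir, f), sep = "\t",
                                      quote = FALSE, row.names = FALSE)
    write_cell_table(cells, file.path(outdir, "cells_qc.tsv"))
    tsv(de$results, "de_results.tsv")
    tsv(de$assessed, "de_assessed.tsv")
    tsv(markers, "markers.tsv")
    tsv(rtab, "recovery_table.tsv")
    tsv(props, "recovery_proportions.tsv")
    tsv(overlap, "recovery_overlap.tsv")
    lfc_df <- data.frame(gene = rownames(lfc),
                         module = if (is.null(modules)) NA_integer_
                                  else unname(modules$clusters[rownames(lfc)]),
                         as.data.frame(lfc, optional = TRUE),
                         check.names = FALSE, stringsAsFactors = FALSE)
    if (!is.null(modules))
      lfc_df <- lfc_df[match(modules$order, lfc_df$gene), , drop = FALSE]
    tsv(lfc_df, "logfc_matrix.tsv")
    comp_df <- data.frame(cluster = rownames(comp),
                          as.data.frame(unclass(comp), optional = TRUE),
                          check.names = FALSE, stringsAsFactors = FALSE)
    tsv(comp_df, "composition.tsv")
    tsv(comp_rec, "composition_recovery.tsv")
    if (!is.null(enr)) tsv(enr, "enrichment.tsv")
  }

  invisible(list(cells = cells, norm = norm, de = de, markers = markers,
                 genes = genes, recovery = rtab, proportions = props,
                 overlap = overlap, logfc = lfc, modules = modules,
                 composition = comp, composition_recovery = comp_rec,
                 enrichment = enr))
}
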