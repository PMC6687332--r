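#' QC and normalization parameters
#'
#' Houses the operational cutoffs for cell filtering: outliers are defined
#' one-sidedly as values above `median + mad_multiplier * mad_scale * MAD`
#' (raw MAD; `mad_scale = 1.4826` makes the product the usual
#' normal-consistent scaled MAD), non-leukocyte clusters are those in which
#' the CD45 gene is detected in fewer than `cd45_min_detection` of cells,
#' and normalization is `ln(1 + scale_factor * count / umi_total)`.
#'
#' @param mad_multiplier k in the median + k * scaled-MAD rule.
#' @param mad_scale MAD consistency constant.
#' @param cd45_gene identifier of the pan-leukocyte marker gene.
#' @param cd45_min_detection minimum fraction of cells detecting
#'   `cd45_gene` for a cluster to be retained (strict less-than drops).
#' @param scale_factor depth-normalization scale (counts per `scale_factor`
#'   total UMI).
#' @param pseudocount pseudocount used on de-logged means in fold changes.
#' @return object of class `qc_params`.
#' @export
qc_params <- function(mad_multiplier = 3, mad_scale = 1.4826,
                      cd45_gene = "Ptprc", cd45_min_detection = 0.05,
                      scale_factor = 1e4, pseudocount = 1) {
  stopifnot(mad_multiplier > 0, scale_factor > 0,
            cd45_min_detection >= 0, cd45_min_detection <= 1)
  structure(list(mad_multiplier = mad_multiplier, mad_scale = mad_scale,
                 cd45_gene = cd45_gene,
                 cd45_min_detection = cd45_min_detection,
                 scale_factor = scale_factor, pseudocount = pseudocount),
            class = "qc_params")
}

#' Compute per-cell QC metrics
#'
#' Adds `umi_total` (column sum), `mito_fraction` (fraction of UMIs from
#' genes whose identifier starts with `mito_prefix`) and an initial
#' `qc_pass` flag to the cell table. Cells with zero total UMI get
#' `mito_fraction = 0` and fail QC outright.
#'
#' @param counts genes x cells count matrix.
#' @param cells cell table with a `barcode` column matching `colnames(counts)`.
#' @param mito_prefix mitochondrial gene-name prefix (mouse convention
#'   `"mt-"`).
#' @return `cells` with columns umi_total, mito_fraction, qc_pass.
#' @export
compute_cell_qc <- function(counts, cells, mito_prefix = "mt-") {
  stopifnot(all(cells$barcode %in% colnames(counts)))
  counts <- counts[, cells$barcode, drop = FALSE]
  umi <- Matrix::colSums(counts)
  mito <- startsWith(rownames(counts), mito_prefix)
  if (!any(mito)) {
    warning("no gene identifiers match prefix '", mito_prefix,
            "'; mito_fraction set to 0")
    mf <- rep(0, ncol(counts))
  } else {
    mf <- ifelse(umi > 0,
                 Matrix::colSums(counts[mito, , drop = FALSE]) / pmax(umi, 1),
                 0)
  }
  cells$umi_total <- as.numeric(umi)
  cells$mito_fraction <- as.numeric(mf)
  cells$qc_pass <- umi > 0
  cells
}

#' Flag high-outlier cells per condition
#'
#' A cell fails QC if its mitochondrial fraction or its UMI total exceeds
#' `median + k * mad_scale * MAD` of that metric, computed within the cell's
#' own condition (each 10x run is filtered on its own distribution). The rule
#' is one-sided: only high outliers are removed. With zero spread (MAD = 0
#' and all values equal) no cell fails on that metric.
#'
#' @param cells cell table from [compute_cell_qc()].
#' @param params a [qc_params()].
#' @return `cells` with `qc_pass` updated; per-condition thresholds attached
#'   as attribute `"thresholds"`.
#' @export
filter_cells <- function(cells, params = qc_params()) {
  stopifnot(all(c("umi_total", "mito_fraction", "qc_pass") %in% names(cells)))
  if (nrow(cells) < 3L) stop("need at least 3 cells to define median/MAD cutoffs")
  k <- params$mad_multiplier * params$mad_scale
  thr <- list()
  for (cond in unique(cells$condition)) {
    idx <- cells$condition == cond
    tm <- median(cells$mito_fraction[idx]) +
      k * mad(cells$mito_fraction[idx], constant = 1)
    tu <- median(cells$umi_total[idx]) +
      k * mad(cells$umi_total[idx], constant = 1)
    fail <- cells$mito_fraction[idx] > tm | cells$umi_total[idx] > tu
    cells$qc_pass[idx] <- cells$qc_pass[idx] & !fail
    thr[[cond]] <- data.frame(condition = cond, mito_threshold = tm,
                              umi_threshold = tu, stringsAsFactors = FALSE)
  }
  attr(cells, "thresholds") <- do.call(rbind, thr)
  cells
}

#' Drop clusters that do not express CD45
#'
#' A cluster is considered non-leukocyte (and all its cells fail QC) when
#' the fraction of its QC-passing cells with a nonzero count of the CD45
#' gene is strictly below `cd45_min_detection`. A cluster exactly at the
#' threshold is retained.
#'
#' @param counts genes x cells count matrix.
#' @param cells cell table with `qc_pass`.
#' @param params a [qc_params()].
#' @return list(retained, dropped, detection, cells): retained/dropped
#'   cluster names, the per-cluster detection rates, and the updated cell
#'   table.
#' @export
exclude_nonleukocyte_clusters <- function(counts, cells, params = qc_params()) {
  gene <- params$cd45_gene
  clusters <- unique(cells$cluster)
  if (!gene %in% rownames(counts)) {
    warning("CD45 gene '", gene, "' not in the gene list; retaining all clusters")
    return(list(retained = clusters, dropped = character(0),
                detection = NULL, cells = cells))
  }
  expr <- counts[gene, cells$barcode] > 0
  det <- vapply(clusters, function(cl) {
    idx <- cells$cluster == cl & cells$qc_pass
    if (!any(idx)) return(NA_real_)
    mean(expr[idx])
  }, 0)
  dropped <- clusters[is.na(det) | det < params$cd45_min_detection]
  retained <- setdiff(clusters, dropped)
  if (!length(retained))
    stop("all clusters fall below the CD45 detection threshold (",
         params$cd45_min_detection, "); check cd45_gene ('", gene, "')")
  cells$qc_pass[cells$cluster %in% dropped] <- FALSE
  list(retained = retained, dropped = dropped,
       detection = data.frame(cluster = clusters, cd45_detection = det,
                              stringsAsFactors = FALSE),
       cells = cells)
}

#' Depth-normalize a count matrix
#'
#' Computes `ln(1 + s * count / umi_total)` per entry, where `s` is the
#' scale factor; zeros map to zero so sparsity is preserved. Apply to
#' QC-passing cells only: a zero-total column is an error here because such
#' cells must already have been excluded.
#'
#' @param counts genes x cells count matrix (QC-passing cells).
#' @param params a [qc_params()].
#' @return dgCMatrix of normalized expression.
#' @export
normalize_counts <- function(counts, params = qc_params()) {
  counts <- as(as(counts, "CsparseMatrix"), "generalMatrix")
  cs <- Matrix::colSums(counts)
  if (any(cs == 0))
    stop("cells with zero total UMI must be removed before normalization")
  norm <- counts
  percol <- rep.int(cs, diff(norm@p))
  norm@x <- log1p(params$scale_factor * norm@x / percol)
  norm
}
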