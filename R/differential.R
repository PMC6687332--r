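#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact null distribution (via [stats::pwilcox()]) when the smaller group
#' has at most 8 observations and there are no ties; otherwise the normal
#' approximation with midranks, tie-corrected variance and continuity
#' correction. With zero rank variance (all observations tied) the p-value
#' is 1.
#'
#' @param a,b numeric vectors, both nonempty.
#' @return two-sided p-value in (0, 1].
#' @export
wilcoxon_test <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) stop("both groups must be nonempty")
  x <- c(a, b)
  r <- rank(x)
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- anyDuplicated(x) > 0L
  if (min(na, nb) <= 8L && !ties) {
    p <- if (U > na * nb / 2)
      pwilcox(U - 1, na, nb, lower.tail = FALSE)
    else
      pwilcox(U, na, nb)
    return(min(1, 2 * p))
  }
  N <- na + nb
  t <- rle(sort(x))$lengths
  sigma2 <- (na * nb / 12) * ((N + 1) - sum(t^3 - t) / (N * (N - 1)))
  if (sigma2 <= 0) return(1)
  z <- U - na * nb / 2
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  min(1, 2 * pnorm(-abs(z)))
}

# row-wise Wilcoxon p-values for a dense matrix split into two column groups
.wilcox_rows <- function(m, ia, ib) {
  vapply(seq_len(nrow(m)),
         function(g) wilcoxon_test(m[g, ia], m[g, ib]), 0)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of raw p-values in \[0, 1\].
#' @return adjusted p-values in the original order, capped at 1 and
#'   elementwise no smaller than the input.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Per-gene mean and detection rate over a cell subset
#'
#' The mean is taken on the de-logged scale (`expm1` of the normalized
#' value, i.e. counts per `scale_factor` UMI); the detection rate is the
#' fraction of cells with a nonzero count.
#'
#' @param norm normalized matrix from [normalize_counts()].
#' @param cols column indices, logical mask, or barcodes of the subset.
#' @return data.frame(gene, mean, pct).
#' @export
condition_stats <- function(norm, cols) {
  sub <- norm[, cols, drop = FALSE]
  if (ncol(sub) == 0L) stop("empty cell subset")
  data.frame(gene = rownames(norm),
             mean = as.numeric(Matrix::rowMeans(expm1(sub))),
             pct = as.numeric(Matrix::rowMeans(sub > 0)),
             stringsAsFactors = FALSE)
}

# shared worker for condition contrasts and one-vs-rest marker contrasts
.contrast_table <- function(norm, cols_a, cols_b, cluster, contrast,
                            pseudocount = 1) {
  sa <- condition_stats(norm, cols_a)
  sb <- condition_stats(norm, cols_b)
  m <- as.matrix(norm[, c(cols_a, cols_b), drop = FALSE])
  ia <- seq_along(cols_a)
  ib <- length(cols_a) + seq_along(cols_b)
  p <- .wilcox_rows(m, ia, ib)
  data.frame(gene = rownames(norm), cluster = cluster, contrast = contrast,
             logFC = log((sa$mean + pseudocount) / (sb$mean + pseudocount)),
             p_raw = p, p_adj = bh_adjust(p),
             mean_a = sa$mean, mean_b = sb$mean,
             pct_a = sa$pct, pct_b = sb$pct,
             stringsAsFactors = FALSE)
}

#' Pairwise differential expression within a cluster
#'
#' For every gene (no effect-size or detection pre-filtering), computes the
#' natural-log fold change of pseudocounted de-logged group means, the
#' two-sided Wilcoxon rank-sum p-value on normalized expression, and the
#' BH-adjusted p-value across all genes of this (cluster, contrast) family.
#' If either condition has fewer than `min_cells` QC-passing cells in the
#' cluster the contrast is not assessable (the absent-in-lean case): a
#' zero-row table is returned with attribute `assessed = FALSE`.
#'
#' @param norm normalized matrix (QC-passing cells).
#' @param cells cell table with barcode, condition, cluster, qc_pass.
#' @param cluster cluster label.
#' @param cond_a,cond_b condition labels; `logFC > 0` means higher in
#'   `cond_a`.
#' @param min_cells minimum cells per group for the contrast to be assessed.
#' @param params a [qc_params()] (pseudocount).
#' @return data.frame(gene, cluster, contrast, logFC, p_raw, p_adj, mean_a,
#'   mean_b, pct_a, pct_b) with attribute `assessed`.
#' @export
de_contrast <- function(norm, cells, cluster, cond_a, cond_b, min_cells = 3L,
                        params = qc_params()) {
  keep <- cells$qc_pass & cells$cluster == cluster
  ba <- cells$barcode[keep & cells$condition == cond_a]
  bb <- cells$barcode[keep & cells$condition == cond_b]
  label <- paste(cond_a, "vs", cond_b)
  if (length(ba) < min_cells || length(bb) < min_cells) {
    out <- data.frame(gene = character(0), cluster = character(0),
                      contrast = character(0), logFC = numeric(0),
                      p_raw = numeric(0), p_adj = numeric(0),
                      mean_a = numeric(0), mean_b = numeric(0),
                      pct_a = numeric(0), pct_b = numeric(0),
                      stringsAsFactors = FALSE)
    attr(out, "assessed") <- FALSE
    attr(out, "n_cells") <- c(a = length(ba), b = length(bb))
    return(out)
  }
  out <- .contrast_table(norm, ba, bb, cluster, label, params$pseudocount)
  attr(out, "assessed") <- TRUE
  attr(out, "n_cells") <- c(a = length(ba), b = length(bb))
  out
}

#' Run all pairwise condition contrasts per cluster
#'
#' @param norm normalized matrix (QC-passing cells).
#' @param cells cell table.
#' @param contrasts list of ordered condition pairs; default the three
#'   pairwise comparisons obese vs lean, CR vs lean, CR vs obese.
#' @param clusters clusters to test (default: all with QC-passing cells).
#' @param min_cells minimum group size per contrast.
#' @param params a [qc_params()].
#' @return list with `results` (row-bound [de_contrast()] tables) and
#'   `assessed` (data.frame: cluster, contrast, assessed, n_a, n_b).
#' @export
run_de <- function(norm, cells,
                   contrasts = list(c("obese", "lean"), c("CR", "lean"),
                                    c("CR", "obese")),
                   clusters = NULL, min_cells = 3L, params = qc_params()) {
  if (is.null(clusters))
    clusters <- sort(unique(cells$cluster[cells$qc_pass]))
  res <- list(); status <- list()
  for (cl in clusters) {
    for (ct in contrasts) {
      r <- de_contrast(norm, cells, cl, ct[1L], ct[2L], min_cells, params)
      n <- attr(r, "n_cells")
      status[[length(status) + 1L]] <- data.frame(
        cluster = cl, contrast = paste(ct[1L], "vs", ct[2L]),
        assessed = attr(r, "assessed"), n_a = n[["a"]], n_b = n[["b"]],
        stringsAsFactors = FALSE)
      if (attr(r, "assessed")) res[[length(res) + 1L]] <- r
    }
  }
  list(results = do.call(rbind, res), assessed = do.call(rbind, status))
}

#' Marker-detection parameters
#'
#' @param min_pct minimum fraction of cells in the cluster expressing the
#'   gene (default 0.25, i.e. expressed in at least 25% of cluster cells).
#' @param direction_up keep only genes higher in the cluster than in the
#'   rest of the cells.
#' @param alpha BH-adjusted significance level.
#' @param min_cells minimum cluster size to test.
#' @return object of class `marker_params`.
#' @export
marker_params <- function(min_pct = 0.25, direction_up = TRUE, alpha = 0.05,
                          min_cells = 3L) {
  stopifnot(min_pct >= 0, min_pct <= 1, alpha > 0, alpha <= 1)
  structure(list(min_pct = min_pct, direction_up = direction_up,
                 alpha = alpha, min_cells = as.integer(min_cells)),
            class = "marker_params")
}

#' Detect cluster marker genes
#'
#' One-vs-rest contrast for each cluster over QC-passing cells; keeps genes
#' detected in at least `min_pct` of the cluster's cells, with positive log
#' fold change over all other cells (when `direction_up`) and BH-adjusted
#' p below `alpha`; ranked by decreasing logFC within each cluster.
#'
#' @param norm normalized matrix.
#' @param cells cell table.
#' @param params a [marker_params()].
#' @param qc a [qc_params()] (pseudocount).
#' @return data.frame(gene, cluster, logFC, p_raw, p_adj, pct_in, pct_out).
#' @export
find_markers <- function(norm, cells, params = marker_params(),
                         qc = qc_params()) {
  cells <- cells[cells$qc_pass, , drop = FALSE]
  clusters <- sort(unique(cells$cluster))
  if (length(clusters) < 2L) stop("marker detection needs at least 2 clusters")
  out <- list()
  for (cl in clusters) {
    bin <- cells$barcode[cells$cluster == cl]
    bout <- cells$barcode[cells$cluster != cl]
    if (length(bin) < params$min_cells) {
      warning("cluster ", cl, " has fewer than ", params$min_cells,
              " cells; skipped")
      next
    }
    r <- .contrast_table(norm, bin, bout, cl, "cluster vs rest",
                         qc$pseudocount)
    keep <- r$pct_a >= params$min_pct & r$p_adj < params$alpha
    if (params$direction_up) keep <- keep & r$logFC > 0
    r <- r[keep, , drop = FALSE]
    r <- r[order(-r$logFC), , drop = FALSE]
    out[[cl]] <- data.frame(gene = r$gene, cluster = r$cluster,
                            logFC = r$logFC, p_raw = r$p_raw, p_adj = r$p_adj,
                            pct_in = r$pct_a, pct_out = r$pct_b,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
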