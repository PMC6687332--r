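#' Gene x cluster log fold-change matrix for coordinated-change analysis
#'
#' Rows are genes whose expression changed at least `fold_threshold`-fold
#' (|logFC| >= ln(fold_threshold), inclusive) in at least one cluster for
#' the given contrast, with BH-adjusted significance below `alpha` in that
#' same cluster; entries are the unthresholded logFC in every assessed
#' cluster, and NA (flagged in attribute `"missing"`) where the contrast was
#' not assessable.
#'
#' @param de [run_de()] output.
#' @param contrast contrast label, e.g. `"obese vs lean"`.
#' @param fold_threshold minimum fold change (default 1.5).
#' @param alpha significance level for the triggering cluster.
#' @return numeric matrix genes x clusters with attribute `"missing"`; a
#'   zero-row matrix (with warning) if no gene passes.
#' @export
coordinated_logfc_matrix <- function(de, contrast = "obese vs lean",
                                     fold_threshold = 1.5, alpha = 0.05) {
  res <- de$results[de$results$contrast == contrast, , drop = FALSE]
  if (!nrow(res)) stop("contrast '", contrast, "' not present in DE results")
  cut <- log(fold_threshold)
  hits <- unique(res$gene[abs(res$logFC) >= cut & res$p_adj < alpha])
  clusters <- sort(unique(de$assessed$cluster[de$assessed$contrast == contrast]))
  if (!length(hits)) {
    warning("no gene reaches |logFC| >= ln(", fold_threshold,
            ") with p_adj < ", alpha)
    m <- matrix(numeric(0), nrow = 0, ncol = length(clusters),
                dimnames = list(NULL, clusters))
    attr(m, "missing") <- m > 0
    return(m)
  }
  hits <- sort(hits)
  m <- matrix(NA_real_, nrow = length(hits), ncol = length(clusters),
              dimnames = list(hits, clusters))
  sub <- res[res$gene %in% hits, , drop = FALSE]
  m[cbind(match(sub$gene, hits), match(sub$cluster, clusters))] <- sub$logFC
  attr(m, "missing") <- is.na(m)
  m
}

# textbook-simple wrapper around stats::hclust; NA entries (clusters where
# the contrast was not assessable) are imputed as 0 = "no change"
#' Hierarchically cluster genes by their cross-cluster fold-change profile
#'
#' Agglomerative clustering of the rows of a [coordinated_logfc_matrix()].
#' Missing entries are imputed as 0 (no change) and reported. With the
#' correlation metric, constant rows have no defined distance and are placed
#' in their own singleton clusters with a warning.
#'
#' @param m genes x clusters numeric matrix.
#' @param linkage agglomeration method passed to [stats::hclust()]
#'   (default `"complete"`).
#' @param metric `"euclidean"` or `"correlation"` (1 - Pearson r).
#' @param k optional number of flat clusters to cut.
#' @return list(hclust, order, genes, clusters, imputed): the `hclust`
#'   object (NULL if fewer than 2 usable rows), leaf order as gene names,
#'   optional flat assignments, and the imputed-entry mask.
#' @export
hierarchical_cluster_genes <- function(m, linkage = "complete",
                                       metric = c("euclidean", "correlation"),
                                       k = NULL) {
  metric <- match.arg(metric)
  if (nrow(m) < 2L) stop("need at least 2 gene rows to cluster")
  imputed <- is.na(m)
  m[imputed] <- 0
  constant <- rep(FALSE, nrow(m))
  if (metric == "correlation") {
    constant <- apply(m, 1L, function(r) stats::sd(r) == 0)
    if (any(constant))
      warning(sum(constant), " constant row(s) have no defined correlation ",
              "distance; placed in singleton clusters")
  }
  use <- which(!constant)
  hc <- NULL
  assign <- rep(NA_integer_, nrow(m))
  ord <- character(0)
  if (length(use) >= 2L) {
    d <- if (metric == "euclidean") dist(m[use, , drop = FALSE])
         else as.dist(1 - cor(t(m[use, , drop = FALSE])))
    hc <- hclust(d, method = linkage)
    ord <- rownames(m)[use][hc$order]
    if (!is.null(k)) assign[use] <- cutree(hc, k = min(k, length(use)))
  } else if (length(use) == 1L) {
    ord <- rownames(m)[use]
    assign[use] <- 1L
  }
  if (any(constant)) {
    extra <- max(assign, 0L, na.rm = TRUE) + seq_len(sum(constant))
    assign[constant] <- extra
    ord <- c(ord, rownames(m)[constant])
  }
  names(assign) <- rownames(m)
  list(hclust = hc, order = ord, genes = rownames(m), clusters = assign,
       imputed = imputed)
}

#' Cluster composition per condition
#'
#' @param cells cell table; only QC-passing cells are counted. Conditions
#'   with zero cells are omitted with a warning.
#' @return clusters x conditions matrix of proportions; each column sums
#'   to 1, absent clusters contribute exactly 0.
#' @export
cluster_composition <- function(cells) {
  cells <- cells[cells$qc_pass, , drop = FALSE]
  conds <- unique(cells$condition)
  tab <- table(factor(cells$cluster), factor(cells$condition, levels = conds))
  empty <- colSums(tab) == 0
  if (any(empty)) {
    warning("condition(s) with zero cells omitted: ",
            paste(colnames(tab)[empty], collapse = ", "))
    tab <- tab[, !empty, drop = FALSE]
  }
  prop <- sweep(unclass(tab), 2L, colSums(tab), "/")
  prop
}

#' Classify cluster-composition trajectories across conditions
#'
#' Applies the gene-level recovery classifier to each cluster's proportion
#' triple (lean, obese, CR): clusters whose obese proportion differs from
#' lean by at most `tau` (relative) are Unchanged; otherwise Recovered maps
#' to RevertedToLean, NotRecovered to RemainedShifted and Different to
#' UniqueToCR (e.g. a cluster absent in lean that expands far beyond its
#' obese share after CR). Clusters absent in all three conditions are
#' dropped.
#'
#' @param comp matrix from [cluster_composition()]; must contain all three
#'   condition columns.
#' @param params a [classifier_params()].
#' @param conditions ordered condition names (lean, obese, CR).
#' @return data.frame(cluster, p_lean, p_obese, p_CR, category).
#' @export
composition_recovery <- function(comp, params = classifier_params(),
                                 conditions = c("lean", "obese", "CR")) {
  if (!all(conditions %in% colnames(comp)))
    stop("composition matrix must contain all of: ",
         paste(conditions, collapse = ", "))
  p <- comp[, conditions, drop = FALSE]
  keep <- rowSums(p) > 0
  p <- p[keep, , drop = FALSE]
  rd <- abs(p[, 2L] - p[, 1L]) / pmax(abs(p[, 1L]), params$epsilon)
  base <- classify_gene(p[, 1L], p[, 2L], p[, 3L], params)
  category <- ifelse(rd <= params$tau, "Unchanged",
                     c(Recovered = "RevertedToLean",
                       NotRecovered = "RemainedShifted",
                       Different = "UniqueToCR")[base])
  data.frame(cluster = rownames(p), p_lean = p[, 1L], p_obese = p[, 2L],
             p_CR = p[, 3L], category = unname(category),
             stringsAsFactors = FALSE, row.names = NULL)
}
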