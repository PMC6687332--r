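#' Recovery-classifier parameters
#'
#' @param tau relative-difference threshold of the Different rule (default
#'   0.10: more than 10% different from both lean and obese).
#' @param epsilon denominator floor on the de-logged mean scale, protecting
#'   the relative difference for silent genes.
#' @param alpha significance level used when selecting genes.
#' @return object of class `classifier_params`. The tie rule (CR mean
#'   exactly equidistant from lean and obese) is fixed to NotRecovered,
#'   conservative toward claiming recovery.
#' @export
classifier_params <- function(tau = 0.10, epsilon = 1e-6, alpha = 0.05) {
  stopifnot(tau > 0, tau < 1, epsilon > 0, alpha > 0, alpha <= 1)
  structure(list(tau = tau, epsilon = epsilon, alpha = alpha,
                 tie_rule = "NotRecovered"),
            class = "classifier_params")
}

#' Classify a gene's CR expression relative to lean and obese
#'
#' Given per-condition mean expression on the de-logged scale (lean `L`,
#' obese `O`, caloric restriction `C`), assigns one of:
#' \describe{
#'   \item{Different}{`C` is not intermediate (outside `[min(L,O), max(L,O)]`)
#'     and its relative difference `|C-X| / max(|X|, epsilon)` exceeds `tau`
#'     for both `X = L` and `X = O`. This rule has precedence: a
#'     non-intermediate value far from both references is its own class even
#'     though it is also strictly closer to one of them.}
#'   \item{Recovered}{otherwise, `C` is strictly closer to lean.}
#'   \item{NotRecovered}{otherwise (closer to obese, or exactly tied).}
#' }
#' The classifier is scale-invariant: multiplying `L`, `O`, `C` by any
#' positive constant leaves the category unchanged (provided values stay
#' above `epsilon`).
#'
#' @param L,O,C nonnegative numeric vectors (recycled to common length) of
#'   per-condition de-logged mean expression.
#' @param params a [classifier_params()].
#' @return character vector of categories.
#' @export
classify_gene <- function(L, O, C, params = classifier_params()) {
  n <- max(length(L), length(O), length(C))
  L <- rep_len(L, n); O <- rep_len(O, n); C <- rep_len(C, n)
  if (any(is.na(L) | is.na(O) | is.na(C))) stop("means must not be NA")
  if (any(L < 0 | O < 0 | C < 0)) stop("means must be nonnegative")
  rd <- function(x, ref) abs(x - ref) / pmax(abs(ref), params$epsilon)
  intermediate <- C >= pmin(L, O) & C <= pmax(L, O)
  different <- !intermediate & rd(C, L) > params$tau & rd(C, O) > params$tau
  ifelse(different, "Different",
         ifelse(abs(C - L) < abs(C - O), "Recovered", "NotRecovered"))
}

#' Select genes differentially expressed in at least one contrast
#'
#' Returns genes with BH-adjusted p below `alpha` in at least one pairwise
#' condition contrast in at least one cluster. All three pairwise contrast
#' families must be present in the input (each assessed in at least one
#' cluster).
#'
#' @param de output of [run_de()].
#' @param alpha significance level.
#' @param required contrast labels that must be present.
#' @return sorted character vector of gene identifiers.
#' @export
select_recovery_genes <- function(de, alpha = 0.05,
                                  required = c("obese vs lean", "CR vs lean",
                                               "CR vs obese")) {
  have <- unique(de$results$contrast)
  missing <- setdiff(required, have)
  if (length(missing))
    stop("missing contrast family: ", paste(missing, collapse = ", "))
  sort(unique(de$results$gene[de$results$p_adj < alpha]))
}

#' Build the per-gene, per-cluster recovery table
#'
#' For every selected gene and every cluster, computes the de-logged mean
#' expression in each condition over QC-passing cells and classifies the
#' triple with [classify_gene()]. Clusters lacking `min_cells` cells in any
#' condition (e.g. the cluster absent in lean) contribute NotAssessed for
#' all genes, with NA means.
#'
#' @param norm normalized matrix (QC-passing cells).
#' @param cells cell table.
#' @param genes selected gene identifiers (see [select_recovery_genes()]).
#' @param params a [classifier_params()].
#' @param min_cells minimum cells per condition for a cluster to be assessed.
#' @param conditions condition labels, ordered (lean, obese, CR).
#' @return data.frame(gene, cluster, L, O, C, category).
#' @export
build_recovery_table <- function(norm, cells, genes,
                                 params = classifier_params(), min_cells = 3L,
                                 conditions = c("lean", "obese", "CR")) {
  if (!length(genes)) {
    warning("empty gene set; returning empty recovery table")
    return(data.frame(gene = character(0), cluster = character(0),
                      L = numeric(0), O = numeric(0), C = numeric(0),
                      category = character(0), stringsAsFactors = FALSE))
  }
  stopifnot(all(genes %in% rownames(norm)))
  cells <- cells[cells$qc_pass, , drop = FALSE]
  clusters <- sort(unique(cells$cluster))
  out <- list()
  for (cl in clusters) {
    idx <- lapply(conditions, function(cc)
      cells$barcode[cells$cluster == cl & cells$condition == cc])
    if (any(vapply(idx, length, 0L) < min_cells)) {
      out[[cl]] <- data.frame(gene = genes, cluster = cl, L = NA_real_,
                              O = NA_real_, C = NA_real_,
                              category = "NotAssessed",
                              stringsAsFactors = FALSE)
      next
    }
    means <- vapply(idx, function(bc)
      as.numeric(Matrix::rowMeans(expm1(norm[genes, bc, drop = FALSE]))),
      numeric(length(genes)))
    out[[cl]] <- data.frame(gene = genes, cluster = cl,
                            L = means[, 1L], O = means[, 2L], C = means[, 3L],
                            category = classify_gene(means[, 1L], means[, 2L],
                                                     means[, 3L], params),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-cluster category proportions
#'
#' Fraction of Recovered / NotRecovered / Different genes among assessed
#' genes in each cluster. The default denominator restricts to genes
#' differentially expressed in the obese-vs-lean contrast within that
#' cluster (the genes obesity actually changed there); `"all_selected"`
#' uses every assessed gene in the table.
#'
#' @param rtab recovery table from [build_recovery_table()].
#' @param denominator `"obese_de_only"` or `"all_selected"`.
#' @param de [run_de()] output; required for `"obese_de_only"`.
#' @param alpha significance level defining DE in the denominator.
#' @return data.frame(cluster, n_genes, Recovered, NotRecovered, Different);
#'   the three fractions sum to 1 per cluster. Clusters with no assessed
#'   genes are omitted with a warning.
#' @export
recovery_proportions <- function(rtab,
                                 denominator = c("obese_de_only",
                                                 "all_selected"),
                                 de = NULL, alpha = 0.05) {
  denominator <- match.arg(denominator)
  if (!nrow(rtab)) stop("empty recovery table")
  assessed <- rtab[rtab$category != "NotAssessed", , drop = FALSE]
  out <- list()
  for (cl in sort(unique(rtab$cluster))) {
    sub <- assessed[assessed$cluster == cl, , drop = FALSE]
    if (denominator == "obese_de_only") {
      if (is.null(de))
        stop("denominator 'obese_de_only' needs the run_de() output")
      deg <- de$results$gene[de$results$cluster == cl &
                               de$results$contrast == "obese vs lean" &
                               de$results$p_adj < alpha]
      sub <- sub[sub$gene %in% deg, , drop = FALSE]
    }
    if (!nrow(sub)) {
      warning("cluster ", cl, " has no assessed genes under denominator '",
              denominator, "'; omitted")
      next
    }
    tab <- table(factor(sub$category,
                        levels = c("Recovered", "NotRecovered", "Different")))
    out[[cl]] <- data.frame(cluster = cl, n_genes = nrow(sub),
                            Recovered = as.numeric(tab["Recovered"]) / nrow(sub),
                            NotRecovered = as.numeric(tab["NotRecovered"]) / nrow(sub),
                            Different = as.numeric(tab["Different"]) / nrow(sub),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cross-cluster sharing of recovery categories
#'
#' For each category, tallies over genes the number of clusters in which the
#' gene carries that category, yielding the histogram of cross-cluster
#' sharing (genes with zero clusters in a category do not contribute to that
#' category's histogram).
#'
#' @param rtab recovery table from [build_recovery_table()].
#' @return data.frame(category, n_clusters, n_genes).
#' @export
cluster_overlap_distribution <- function(rtab) {
  assessed <- rtab[rtab$category != "NotAssessed", , drop = FALSE]
  out <- list()
  for (cat in c("Recovered", "NotRecovered", "Different")) {
    cnt <- table(assessed$gene[assessed$category == cat])
    if (!length(cnt)) next
    h <- table(factor(as.integer(cnt), levels = seq_len(max(cnt))))
    out[[cat]] <- data.frame(category = cat,
                             n_clusters = as.integer(names(h)),
                             n_genes = as.integer(h),
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
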