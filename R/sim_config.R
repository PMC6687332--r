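#' Default per-cluster composition across the three dietary conditions
#'
#' Builds a cluster x condition matrix of cell-type proportions encoding the
#' composition motifs the pipeline is designed to detect: cluster 1 expands
#' in obesity and reverts after caloric restriction (0.16 / 0.38 / 0.17 of
#' cells), the last cluster is absent in lean animals and strongly enriched
#' after CR (0 / 0.07 / 0.30), and the remaining mass is spread evenly over
#' the other clusters.
#'
#' @param n_clusters number of clusters (>= 3).
#' @param conditions condition names; the first is treated as lean, the
#'   second as obese, the third as CR.
#' @return numeric matrix with `n_clusters` rows and one column per
#'   condition; every column sums to 1.
#' @export
default_cluster_proportions <- function(n_clusters = 15,
                                        conditions = c("lean", "obese", "CR")) {
  stopifnot(n_clusters >= 3, length(conditions) == 3)
  p <- matrix(0, nrow = n_clusters, ncol = 3,
              dimnames = list(paste0("C", seq_len(n_clusters)), conditions))
  motif <- rbind(lean = c(0.16, 0.00), obese = c(0.38, 0.07), CR = c(0.17, 0.30))
  mid <- seq_len(n_clusters)[-c(1L, n_clusters)]
  for (j in 1:3) {
    p[1L, j] <- motif[j, 1L]
    p[n_clusters, j] <- motif[j, 2L]
    p[mid, j] <- (1 - sum(motif[j, ])) / length(mid)
  }
  p
}

#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic-data generator.
#' Defaults mirror the scale of a three-condition mouse visceral-adipose
#' leukocyte experiment: 2268 / 5232 / 2458 cells in lean / obese / CR, 15
#' clusters with one absent in lean, and ~2000 (variable) genes.
#'
#' Expression is negative binomial per gene with lognormal per-cell size
#' factors (sigma = 0.3). Planted differentially expressed genes receive
#' condition means (L*, O*, C*) that satisfy their category under the
#' recovery classifier by construction: Recovered genes return to the lean
#' mean after CR, NotRecovered genes stay at the obese mean, and Different
#' genes land at `max(L*, O*) * divergence_fold`, outside the lean-obese
#' interval and more than the classifier threshold away from both.
#'
#' @param n_genes total number of genes simulated (the generator emulates the
#'   variable-gene subset of a full transcriptome, not all genes).
#' @param n_clusters number of leukocyte clusters.
#' @param cells_per_condition named integer vector of cells per condition.
#' @param cluster_proportions cluster x condition matrix of label
#'   probabilities; columns must sum to 1. At least one cluster must have
#'   probability 0 in the first (lean) condition and > 0 in the others.
#' @param baseline_mean per-gene negative-binomial mean scale (UMI per cell).
#' @param dispersion negative-binomial size parameter within a
#'   cluster-condition group (larger = less overdispersed).
#' @param n_planted_per_category named counts of planted genes for the
#'   Recovered, NotRecovered and Different categories.
#' @param effect_fold planted obese-vs-lean fold change (>= 1.5).
#' @param divergence_fold planted CR departure for Different genes (> 1.1).
#' @param n_marker_genes cluster-specific marker genes planted per cluster.
#' @param marker_fold expression fold elevation of a marker gene in its own
#'   cluster relative to all other clusters.
#' @param mito_gene_fraction fraction of genes given the mitochondrial
#'   (`mt-`) prefix.
#' @param n_outlier_cells number of planted high-mitochondrial cells.
#' @param n_doublets number of planted doublets (cells replaced by the
#'   element-wise sum of two same-condition cells).
#' @param seed integer seed; identical configs give identical datasets.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 2000,
                       n_clusters = 15,
                       cells_per_condition = c(lean = 2268, obese = 5232, CR = 2458),
                       cluster_proportions = default_cluster_proportions(n_clusters,
                         names(cells_per_condition)),
                       baseline_mean = 8,
                       dispersion = 10,
                       n_planted_per_category = c(Recovered = 100,
                                                  NotRecovered = 100,
                                                  Different = 100),
                       effect_fold = 2,
                       divergence_fold = 1.5,
                       n_marker_genes = 10,
                       marker_fold = 4,
                       mito_gene_fraction = 0.02,
                       n_outlier_cells = 100,
                       n_doublets = 50,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_clusters = as.integer(n_clusters),
              cells_per_condition = cells_per_condition,
              cluster_proportions = cluster_proportions,
              baseline_mean = baseline_mean,
              dispersion = dispersion,
              n_planted_per_category = n_planted_per_category,
              effect_fold = effect_fold,
              divergence_fold = divergence_fold,
              n_marker_genes = as.integer(n_marker_genes),
              marker_fold = marker_fold,
              mito_gene_fraction = mito_gene_fraction,
              n_outlier_cells = as.integer(n_outlier_cells),
              n_doublets = as.integer(n_doublets),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks the structural invariants of a [sim_config()]: probability columns
#' sum to 1, at least one cluster is absent in lean but present in obese and
#' CR, planted gene counts fit inside `n_genes`, and effect sizes are in
#' their admissible ranges.
#'
#' @param cfg a `sim_config`.
#' @return `cfg`, invisibly; errors describe the violated invariant.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  conds <- names(cfg$cells_per_condition)
  if (length(conds) != 3L || anyDuplicated(conds))
    stop("cells_per_condition must name exactly three distinct conditions")
  p <- cfg$cluster_proportions
  if (!is.matrix(p) || nrow(p) != cfg$n_clusters || ncol(p) != 3L)
    stop("cluster_proportions must be an n_clusters x 3 matrix")
  if (!identical(colnames(p), conds))
    stop("cluster_proportions columns must match names(cells_per_condition)")
  if (any(p < 0) || any(abs(colSums(p) - 1) > 1e-9))
    stop("each cluster_proportions column must be a probability vector summing to 1")
  absent <- p[, 1L] == 0 & p[, 2L] > 0 & p[, 3L] > 0
  if (!any(absent))
    stop("at least one cluster must have proportion 0 in ", conds[1L],
         " and > 0 in the other conditions")
  npl <- cfg$n_planted_per_category
  if (!all(c("Recovered", "NotRecovered", "Different") %in% names(npl)))
    stop("n_planted_per_category must name Recovered, NotRecovered and Different")
  n_mito <- round(cfg$mito_gene_fraction * cfg$n_genes)
  reserved <- sum(npl) + n_mito + cfg$n_clusters * cfg$n_marker_genes + 1L
  if (reserved >= cfg$n_genes)
    stop("planted + marker + mitochondrial genes (", reserved,
         ") must total fewer than n_genes (", cfg$n_genes, ")")
  if (cfg$effect_fold < 1.5) stop("effect_fold must be >= 1.5")
  if (cfg$divergence_fold <= 1.1) stop("divergence_fold must be > 1.1")
  if (cfg$mito_gene_fraction < 0 || cfg$mito_gene_fraction > 1)
    stop("mito_gene_fraction must be in [0, 1]")
  if (cfg$baseline_mean <= 0 || cfg$dispersion <= 0)
    stop("baseline_mean and dispersion must be positive")
  if (any(cfg$cells_per_condition == 0) && sum(npl) > 0)
    stop("condition ", paste(conds[cfg$cells_per_condition == 0], collapse = ", "),
         " has zero cells but planted effects were requested")
  invisible(cfg)
}

#' Write / read a simulation configuration as YAML
#'
#' @param cfg a `sim_config`.
#' @param path file path.
#' @return `write_sim_config` returns `path` invisibly; `read_sim_config`
#'   returns a validated `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  x <- unclass(cfg)
  # yaml drops names on atomic vectors; named lists map cleanly
  x$cells_per_condition <- as.list(cfg$cells_per_condition)
  x$n_planted_per_category <- as.list(cfg$n_planted_per_category)
  x$cluster_proportions <- list(
    clusters = rownames(cfg$cluster_proportions),
    conditions = colnames(cfg$cluster_proportions),
    values = apply(cfg$cluster_proportions, 2L, as.numeric, simplify = FALSE))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  cp <- x$cluster_proportions
  m <- do.call(cbind, cp$values)
  dimnames(m) <- list(cp$clusters, cp$conditions)
  x$cluster_proportions <- m
  x$cells_per_condition <- unlist(x$cells_per_condition)
  x$n_planted_per_category <- unlist(x$n_planted_per_category)
  cfg <- structure(x, class = "sim_config")
  validate_sim_config(cfg)
  cfg
}
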