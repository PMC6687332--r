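#' Generate a three-condition clustered UMI count matrix with planted truth
#'
#' Draws a sparse genes x cells count matrix under a negative-binomial model
#' with lognormal per-cell size factors. Cells are assigned to clusters by
#' sampling each condition's cluster proportions, so a cluster with
#' proportion 0 in lean never receives a lean cell. Gene roles:
#' \itemize{
#'   \item one constitutive CD45 gene (`Ptprc`) expressed in all clusters;
#'   \item mitochondrial genes carrying the `mt-` prefix;
#'   \item `n_marker_genes` cluster-specific markers per cluster, elevated
#'     `marker_fold`-fold in their own cluster in every condition;
#'   \item planted differentially expressed genes whose condition means
#'     (L*, O*, C*) encode the Recovered / NotRecovered / Different
#'     categories (effects apply in all clusters);
#'   \item the remainder are null genes with no condition or cluster effect.
#' }
#' The planted (L*, O*, C*) triples are checked against
#' [classify_gene()] at construction time, so the planted category is sound
#' by definition, not by sampling luck.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `counts` (dgCMatrix genes x cells), `cells`
#'   (data.frame: barcode, condition, cluster) and `truth` (a `truth_table`
#'   list with per-gene and per-cell ground truth and the planted cluster
#'   proportions).
#' @export
generate_dataset <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  conds <- names(cfg$cells_per_condition)
  G <- cfg$n_genes
  K <- cfg$n_clusters

  n_mito <- round(cfg$mito_gene_fraction * G)
  n_marker <- K * cfg$n_marker_genes
  npl <- cfg$n_planted_per_category[c("Recovered", "NotRecovered", "Different")]

  gene_names <- sprintf("Gene%05d", seq_len(G))
  gene_names[1L] <- "Ptprc"
  if (n_mito > 0)
    gene_names[2L:(1L + n_mito)] <- sprintf("mt-Gene%03d", seq_len(n_mito))
  role <- rep("null", G)
  role[1L] <- "cd45"
  if (n_mito > 0) role[2L:(1L + n_mito)] <- "mito"
  i0 <- 1L + n_mito
  marker_idx <- if (n_marker > 0) i0 + seq_len(n_marker) else integer(0)
  role[marker_idx] <- "marker"
  i0 <- i0 + n_marker
  planted_idx <- i0 + seq_len(sum(npl))
  role[planted_idx] <- "planted"
  category <- rep("Null", G)
  category[planted_idx] <- rep(names(npl), npl)
  marker_cluster <- rep(NA_character_, G)
  marker_cluster[marker_idx] <- rep(rownames(cfg$cluster_proportions),
                                    each = cfg$n_marker_genes)

  # per-gene baseline means: moderate band for genes carrying planted
  # structure (keeps effects estimable), heavier-tailed lognormal for nulls,
  # uniformly high expression for mitochondrial genes (as in real cells)
  lambda <- cfg$baseline_mean * rlnorm(G, meanlog = -0.32, sdlog = 0.8)
  band <- role == "marker"
  lambda[band] <- cfg$baseline_mean * runif(sum(band), 0.75, 1.5)
  lambda[role == "mito"] <- cfg$baseline_mean *
    runif(sum(role == "mito"), 1.5, 2.5)
  lambda[1L] <- cfg$baseline_mean * 2

  # condition means L*, O*, C* (equal to lambda for non-planted genes).
  # Planted effects are mass-balanced: genes come in up/down pairs whose
  # lean and obese totals are exactly equal (the pair swaps its masses),
  # and Different genes are split between above-both and below-both
  # placements in the ratio that cancels their net CR excess. Without this
  # balancing, planted effects change a condition's total library size and
  # depth normalization converts that into a spurious shift of every other
  # gene in that condition.
  L <- O <- C <- lambda
  f <- cfg$effect_fold
  d <- cfg$divergence_fold
  for (cat in names(npl)) {
    idx <- planted_idx[category[planted_idx] == cat]
    n <- length(idx)
    if (!n) next
    base <- cfg$baseline_mean * runif(ceiling(n / 2), 0.75, 1.5)
    m <- rep(base, each = 2L, length.out = n)
    up <- rep(c(TRUE, FALSE), length.out = n)
    L[idx] <- ifelse(up, m, f * m)
    O[idx] <- ifelse(up, f * m, m)
    if (cat == "Recovered") C[idx] <- L[idx]
    if (cat == "NotRecovered") C[idx] <- O[idx]
    if (cat == "Different") {
      excess_above <- 2 * f * d - (1 + f)     # CR mass excess per above-pair
      deficit_below <- (1 + f) - 2 / d        # CR mass deficit per below-pair
      # below-both placement is only admissible when it clears the
      # classifier's relative-difference threshold (1 - 1/d > tau)
      below_ok <- (1 - 1 / d) > classifier_params()$tau
      frac_above <- if (!below_ok || excess_above <= 0) 1 else
        if (deficit_below <= 0) 0 else
        deficit_below / (excess_above + deficit_below)
      pairs <- ceiling(n / 2)
      above <- rep(rep(c(TRUE, FALSE),
                       c(round(pairs * frac_above),
                         pairs - round(pairs * frac_above))),
                   each = 2L, length.out = n)
      C[idx] <- ifelse(above, pmax(L[idx], O[idx]) * d,
                       pmin(L[idx], O[idx]) / d)
    }
  }
  chk <- classify_gene(L[planted_idx], O[planted_idx], C[planted_idx])
  if (!identical(chk, category[planted_idx]))
    stop("internal error: planted condition means violate their category")

  cond_mean <- cbind(L, O, C)
  colnames(cond_mean) <- conds

  # cluster multipliers (marker structure, condition-independent)
  mult <- matrix(1, nrow = G, ncol = K,
                 dimnames = list(NULL, rownames(cfg$cluster_proportions)))
  if (n_marker > 0)
    mult[cbind(marker_idx, rep(seq_len(K), each = cfg$n_marker_genes))] <-
      cfg$marker_fold

  blocks <- vector("list", length(conds))
  cells <- vector("list", length(conds))
  for (j in seq_along(conds)) {
    n <- cfg$cells_per_condition[[j]]
    if (n == 0) next
    kl <- sample.int(K, n, replace = TRUE, prob = cfg$cluster_proportions[, j])
    sf <- rlnorm(n, meanlog = -0.045, sdlog = 0.3)
    mu <- (cond_mean[, j] * mult[, kl, drop = FALSE]) *
      rep(sf, each = G)
    cnt <- matrix(rnbinom(G * n, mu = as.vector(mu), size = cfg$dispersion),
                  nrow = G)
    blocks[[j]] <- Matrix::Matrix(cnt, sparse = TRUE)
    cells[[j]] <- data.frame(
      barcode = sprintf("%s_%04d", conds[j], seq_len(n)),
      condition = conds[j],
      cluster = rownames(cfg$cluster_proportions)[kl],
      stringsAsFactors = FALSE)
  }
  counts <- do.call(cbind, blocks[!vapply(blocks, is.null, TRUE)])
  cells <- do.call(rbind, cells[!vapply(cells, is.null, TRUE)])
  dimnames(counts) <- list(gene_names, cells$barcode)

  truth <- list(
    genes = data.frame(gene = gene_names, role = role, category = category,
                       marker_cluster = marker_cluster,
                       mean_lean = cond_mean[, 1L], mean_obese = cond_mean[, 2L],
                       mean_CR = cond_mean[, 3L], stringsAsFactors = FALSE),
    cells = data.frame(barcode = cells$barcode, is_planted_outlier = FALSE,
                       outlier_kind = NA_character_,
                       doublet_partner = NA_character_,
                       stringsAsFactors = FALSE),
    proportions = cfg$cluster_proportions,
    affected_clusters = rownames(cfg$cluster_proportions))
  class(truth) <- "truth_table"
  list(counts = counts, cells = cells, truth = truth)
}

#' Plant high-mitochondrial outlier cells and doublets
#'
#' Converts `cfg$n_outlier_cells` randomly chosen cells into apoptotic-like
#' cells by inflating their mitochondrial counts until the mitochondrial
#' fraction reaches `max(0.25, 6 x cohort median)` (well above the 5x-median
#' contract and any median + 3 MAD cutoff), and converts `cfg$n_doublets`
#' cells into doublets by adding the full count vector of another cell from
#' the same condition. Doublet hosts and partners are drawn from the deepest
#' third of each condition's UMI distribution: a real detectable doublet has
#' roughly double depth, whereas the sum of two shallow cells is
#' statistically indistinguishable from one deep singlet under the lognormal
#' depth law and would make the planted truth unlearnable.
#'
#' Reseeds deterministically from `cfg$seed + 1`, so planting is reproducible
#' independent of when the dataset was generated.
#'
#' @param counts genes x cells count matrix (dgCMatrix).
#' @param cells cell table with `barcode` and `condition`.
#' @param cfg a [sim_config()].
#' @param truth optional `truth_table` to update (per-cell flags).
#' @param mito_prefix prefix identifying mitochondrial genes.
#' @return list(counts, cells, truth) with planted outliers flagged in
#'   `truth$cells`.
#' @export
plant_outliers <- function(counts, cells, cfg, truth = NULL,
                           mito_prefix = "mt-") {
  stopifnot(ncol(counts) == nrow(cells))
  if (is.null(truth)) {
    truth <- list(genes = NULL, cells = data.frame(
      barcode = cells$barcode, is_planted_outlier = FALSE,
      outlier_kind = NA_character_, doublet_partner = NA_character_,
      stringsAsFactors = FALSE))
    class(truth) <- "truth_table"
  }
  n_out <- cfg$n_outlier_cells
  n_dbl <- cfg$n_doublets
  if (n_out == 0 && n_dbl == 0) return(list(counts = counts, cells = cells,
                                            truth = truth))
  if (n_out + n_dbl > ncol(counts))
    stop("n_outlier_cells + n_doublets exceeds the number of cells")
  mito <- startsWith(rownames(counts), mito_prefix)
  if (!any(mito) && n_out > 0)
    stop("mito_gene_fraction is 0 (no '", mito_prefix,
         "' genes) but n_outlier_cells > 0")
  set.seed(cfg$seed + 1L)

  umi <- Matrix::colSums(counts)
  counts <- as(counts, "CsparseMatrix")

  # high-mitochondrial cells
  mito_hosts <- integer(0)
  if (n_out > 0) {
    mito_frac <- Matrix::colSums(counts[mito, , drop = FALSE]) / pmax(umi, 1)
    target <- max(0.25, 6 * median(mito_frac))
    if (target >= 0.9) target <- 0.9
    mito_hosts <- sample.int(ncol(counts), n_out)
    dense_mito <- as.matrix(counts[mito, mito_hosts, drop = FALSE])
    for (h in seq_along(mito_hosts)) {
      col <- dense_mito[, h]
      other <- umi[mito_hosts[h]] - sum(col)
      need <- target / (1 - target) * max(other, 1)
      if (sum(col) == 0) {
        col <- rep(ceiling(need / length(col)), length(col))
      } else {
        col <- round(col * need / sum(col))
        col[which.max(col)] <- col[which.max(col)] + max(0, ceiling(need) - sum(col))
      }
      dense_mito[, h] <- col
    }
    counts[mito, mito_hosts] <- dense_mito
  }

  # doublets: host column += partner column, same condition, deep cells
  dbl_hosts <- integer(0)
  if (n_dbl > 0) {
    conds <- unique(cells$condition)
    n_by_cond <- vapply(conds, function(cc) sum(cells$condition == cc), 0)
    alloc <- floor(n_dbl * n_by_cond / sum(n_by_cond))
    rem <- n_dbl - sum(alloc)
    if (rem > 0) {
      o <- order(n_dbl * n_by_cond / sum(n_by_cond) - alloc, decreasing = TRUE)
      alloc[o[seq_len(rem)]] <- alloc[o[seq_len(rem)]] + 1L
    }
    for (j in seq_along(conds)) {
      if (alloc[j] == 0) next
      in_cond <- which(cells$condition == conds[j])
      in_cond <- setdiff(in_cond, mito_hosts)
      deep <- in_cond[umi[in_cond] >= quantile(umi[in_cond], 2 / 3)]
      if (length(deep) < 2L * alloc[j])
        stop("not enough deep cells in condition ", conds[j],
             " to plant ", alloc[j], " doublets")
      pick <- sample(deep, 2L * alloc[j])
      hosts <- pick[seq_len(alloc[j])]
      partners <- pick[alloc[j] + seq_len(alloc[j])]
      counts[, hosts] <- counts[, hosts, drop = FALSE] +
        counts[, partners, drop = FALSE]
      truth$cells$doublet_partner[hosts] <- cells$barcode[partners]
      dbl_hosts <- c(dbl_hosts, hosts)
    }
  }

  truth$cells$is_planted_outlier[mito_hosts] <- TRUE
  truth$cells$outlier_kind[mito_hosts] <- "high_mito"
  truth$cells$is_planted_outlier[dbl_hosts] <- TRUE
  truth$cells$outlier_kind[dbl_hosts] <- "doublet"
  list(counts = as(counts, "CsparseMatrix"), cells = cells, truth = truth)
}

#' Generate a dataset and plant its outliers in one call
#'
#' @param cfg a [sim_config()].
#' @return as [generate_dataset()], with outlier cells and doublets planted
#'   per `cfg`.
#' @export
simulate_dataset <- function(cfg) {
  d <- generate_dataset(cfg)
  p <- plant_outliers(d$counts, d$cells, cfg, truth = d$truth)
  list(counts = p$counts, cells = p$cells, truth = p$truth)
}

#' Summarize planted ground truth
#'
#' @param truth a `truth_table`.
#' @return data.frame with one row per planted category: the number of
#'   planted genes, the number of clusters the effect applies to, and the
#'   planted outlier-cell counts as an `outliers` attribute.
#' @export
truth_summary <- function(truth) {
  stopifnot(inherits(truth, "truth_table"))
  cats <- c("Recovered", "NotRecovered", "Different")
  n <- if (is.null(truth$genes)) rep(0L, 3L) else
    vapply(cats, function(cc) sum(truth$genes$category == cc), 0L)
  out <- data.frame(category = cats, n_genes = as.integer(n),
                    n_clusters_affected = length(truth$affected_clusters),
                    stringsAsFactors = FALSE)
  kinds <- c("high_mito", "doublet")
  n_out <- vapply(kinds, function(kk)
    sum(!is.na(truth$cells$outlier_kind) & truth$cells$outlier_kind == kk), 0L)
  attr(out, "outliers") <- data.frame(outlier_kind = kinds,
                                      n_cells = as.integer(n_out),
                                      stringsAsFactors = FALSE)
  out
}

#' Write a simulated dataset to disk as plain-text artifacts
#'
#' Writes the count matrix as a MatrixMarket triplet with gene/barcode
#' sidecars, the cell table and truth tables as TSV, the configuration as
#' YAML, and a GMT gene-set collection built from the planted gene groups
#' (one set per planted category, one per cluster's markers) for use with
#' the enrichment stage.
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory (created if missing).
#' @param cfg the [sim_config()] used (written as `config.yaml` if given).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir, cfg = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_counts(sim$counts, dir, format = "mtx_triplet")
  write_cell_table(sim$cells, file.path(dir, "cells.tsv"))
  if (!is.null(sim$truth$genes))
    write.table(sim$truth$genes, file.path(dir, "truth_genes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$truth$cells, file.path(dir, "truth_cells.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cfg)) write_sim_config(cfg, file.path(dir, "config.yaml"))
  if (!is.null(sim$truth$genes)) {
    g <- sim$truth$genes
    sets <- list(planted_recovered = g$gene[g$category == "Recovered"],
                 planted_notrecovered = g$gene[g$category == "NotRecovered"],
                 planted_different = g$gene[g$category == "Different"])
    for (cl in unique(stats::na.omit(g$marker_cluster)))
      sets[[paste0("markers_", cl)]] <-
        g$gene[!is.na(g$marker_cluster) & g$marker_cluster == cl]
    sets <- sets[vapply(sets, length, 0L) > 0]
    if (length(sets))
      write_gmt(sets, file.path(dir, "gene_sets.gmt"),
                descriptions = rep("planted synthetic gene set", length(sets)))
  }
  invisible(dir)
}
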