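# Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

# Parameter-recovery study conditions: 5 clusters (one absent in lean),
# ~200 cells per cluster-condition, 2000 genes, 300 planted at 2-fold.
recovery_cfg <- function(seed = 42L) {
  prop <- cbind(lean = c(0.25, 0.25, 0.25, 0.25, 0),
                obese = rep(0.2, 5), CR = rep(0.2, 5))
  rownames(prop) <- paste0("C", 1:5)
  sim_config(n_genes = 2000, n_clusters = 5,
             cells_per_condition = c(lean = 800, obese = 1000, CR = 1000),
             cluster_proportions = prop,
             n_outlier_cells = 20, n_doublets = 10, seed = seed)
}

recovery_sim <- function() {
  if (is.null(.fixtures$sim)) .fixtures$sim <- simulate_dataset(recovery_cfg())
  .fixtures$sim
}

recovery_pipeline <- function() {
  if (is.null(.fixtures$pipe)) {
    sim <- recovery_sim()
    .fixtures$pipe <- suppressWarnings(
      run_pipeline(sim$counts, sim$cells, outdir = NULL))
  }
  .fixtures$pipe
}

# small dataset for structural unit tests
tiny_cfg <- function(seed = 7L, n_outlier_cells = 6, n_doublets = 3, ...) {
  prop <- cbind(lean = c(0.3, 0.35, 0.35, 0),
                obese = c(0.3, 0.3, 0.3, 0.1), CR = c(0.2, 0.3, 0.2, 0.3))
  rownames(prop) <- paste0("C", 1:4)
  sim_config(n_genes = 300, n_clusters = 4,
             cells_per_condition = c(lean = 150, obese = 180, CR = 180),
             cluster_proportions = prop,
             n_planted_per_category = c(Recovered = 12, NotRecovered = 12,
                                        Different = 12),
             n_marker_genes = 5, n_outlier_cells = n_outlier_cells,
             n_doublets = n_doublets, seed = seed, ...)
}

tiny_sim <- function() {
  if (is.null(.fixtures$tiny)) .fixtures$tiny <- simulate_dataset(tiny_cfg())
  .fixtures$tiny
}

# toy count matrix with hand-set entries (genes x cells)
toy_counts <- function(m, genes = NULL, barcodes = NULL) {
  if (is.null(genes))
    genes <- if (!is.null(rownames(m))) rownames(m)
             else paste0("g", seq_len(nrow(m)))
  if (is.null(barcodes))
    barcodes <- if (!is.null(colnames(m))) colnames(m)
                else paste0("c", seq_len(ncol(m)))
  dimnames(m) <- list(genes, barcodes)
  methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
}
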