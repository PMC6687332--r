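test_that("identical config and seed give byte-identical datasets", {
  cfg <- tiny_cfg(seed = 7L)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))
  expect_identical(a$cells, b$cells)
  expect_identical(a$truth$genes, b$truth$genes)
  expect_identical(a$truth$cells, b$truth$cells)
})

test_that("a cluster with zero lean proportion receives no lean cells", {
  sim <- tiny_sim()
  lean <- sim$cells[sim$cells$condition == "lean", ]
  expect_false("C4" %in% lean$cluster)
  expect_true("C4" %in% sim$cells$cluster[sim$cells$condition == "obese"])
})

test_that("planted condition means satisfy their category by construction", {
  tg <- recovery_sim()$truth$genes
  pl <- tg[tg$role == "planted", ]
  expect_identical(classify_gene(pl$mean_lean, pl$mean_obese, pl$mean_CR),
                   pl$category)
})

test_that("empirical condition means track planted means within NB noise", {
  sim <- recovery_sim()
  tg <- sim$truth$genes
  pl <- tg[tg$role == "planted", ]
  clean <- !sim$truth$cells$is_planted_outlier
  ok <- rep(TRUE, nrow(pl))
  for (cond in c("lean", "obese", "CR")) {
    idx <- sim$cells$condition == cond & clean
    emp <- Matrix::rowMeans(sim$counts[pl$gene, idx, drop = FALSE])
    planted <- pl[[paste0("mean_", cond)]]
    ok <- ok & abs(emp - planted) / planted < 0.10
  }
  expect_gte(mean(ok), 0.95)
})

test_that("planted effects leave the per-condition library mass balanced", {
  tg <- recovery_sim()$truth$genes
  totals <- c(sum(tg$mean_lean), sum(tg$mean_obese), sum(tg$mean_CR))
  expect_lt(max(totals) / min(totals) - 1, 0.01)
})

test_that("plant_outliers is the identity when nothing is requested", {
  cfg <- tiny_cfg(seed = 3L, n_outlier_cells = 0, n_doublets = 0)
  d <- generate_dataset(cfg)
  p <- plant_outliers(d$counts, d$cells, cfg, truth = d$truth)
  expect_identical(as.matrix(p$counts), as.matrix(d$counts))
  expect_false(any(p$truth$cells$is_planted_outlier))
})

test_that("a planted doublet's UMI total is the sum of its two source cells", {
  d <- generate_dataset(tiny_cfg())
  before <- Matrix::colSums(d$counts)
  p <- plant_outliers(d$counts, d$cells, tiny_cfg(), truth = d$truth)
  tc <- p$truth$cells
  hosts <- which(!is.na(tc$outlier_kind) & tc$outlier_kind == "doublet")
  expect_length(hosts, tiny_cfg()$n_doublets)
  after <- Matrix::colSums(p$counts)
  for (h in hosts) {
    partner <- match(tc$doublet_partner[h], d$cells$barcode)
    expect_equal(after[h], before[h] + before[partner])
  }
})

test_that("planted high-mito cells exceed five times the cohort median fraction", {
  sim <- tiny_sim()
  qc <- compute_cell_qc(sim$counts, sim$cells)
  kind <- sim$truth$cells$outlier_kind
  hi <- !is.na(kind) & kind == "high_mito"
  expect_true(all(qc$mito_fraction[hi] > 5 * median(qc$mito_fraction)))
})

test_that("planting outliers without mitochondrial genes is rejected", {
  cfg <- tiny_cfg(seed = 9L, mito_gene_fraction = 0)
  d <- generate_dataset(cfg)
  expect_error(plant_outliers(d$counts, d$cells, cfg, truth = d$truth),
               "mito_gene_fraction")
})

test_that("a condition with zero cells but planted effects is rejected", {
  expect_error(
    sim_config(n_genes = 300, n_clusters = 4,
               cells_per_condition = c(lean = 0, obese = 100, CR = 100),
               cluster_proportions = tiny_cfg()$cluster_proportions,
               n_planted_per_category = c(Recovered = 12, NotRecovered = 12,
                                          Different = 12),
               n_marker_genes = 5),
    "zero cells")
})

test_that("truth_summary counts planted genes and outliers exactly", {
  sim <- tiny_sim()
  s <- truth_summary(sim$truth)
  expect_equal(s$n_genes[match(c("Recovered", "NotRecovered", "Different"),
                               s$category)],
               c(12L, 12L, 12L))
  out <- attr(s, "outliers")
  expect_equal(out$n_cells[out$outlier_kind == "high_mito"], 6L)
  expect_equal(out$n_cells[out$outlier_kind == "doublet"], 3L)

  empty <- structure(list(genes = NULL,
                          cells = data.frame(barcode = character(0),
                                             is_planted_outlier = logical(0),
                                             outlier_kind = character(0))),
                     class = "truth_table")
  expect_true(all(truth_summary(empty)$n_genes == 0))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(cluster_proportions = matrix(1, 15, 3,
    dimnames = list(NULL, c("lean", "obese", "CR")))), "summing to 1")
  p <- default_cluster_proportions(5)
  p[5, 1] <- 0.05; p[1, 1] <- p[1, 1] - 0.05
  expect_error(sim_config(n_clusters = 5, cluster_proportions = p),
               "proportion 0")
  expect_error(sim_config(effect_fold = 1.2), "effect_fold")
  expect_error(sim_config(divergence_fold = 1.05), "divergence_fold")
  expect_error(sim_config(n_genes = 100), "fewer than n_genes")
})

test_that("configs round-trip through YAML", {
  cfg <- tiny_cfg()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(back$cluster_proportions, cfg$cluster_proportions)
  expect_equal(back$cells_per_condition, cfg$cells_per_condition)
  expect_equal(back$seed, cfg$seed)
})
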