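test_that("classify_gene follows the closeness and 10%-difference rules", {
  expect_equal(classify_gene(10, 20, 11), "Recovered")
  expect_equal(classify_gene(10, 20, 19), "NotRecovered")
  # non-intermediate and >10% from both lean and obese
  expect_equal(classify_gene(10, 20, 25), "Different")
  # non-intermediate but within 10% of obese: falls back to closeness
  expect_equal(classify_gene(10, 20, 20.5), "NotRecovered")
  # exact tie goes to NotRecovered (conservative toward claiming recovery)
  expect_equal(classify_gene(10, 20, 15), "NotRecovered")
  expect_error(classify_gene(-1, 2, 3), "nonnegative")
})

test_that("classify_gene is invariant under positive rescaling", {
  set.seed(31)
  for (i in 1:200) {
    x <- runif(3, 0.01, 30)
    s <- runif(1, 0.1, 100)
    expect_identical(classify_gene(x[1], x[2], x[3]),
                     classify_gene(s * x[1], s * x[2], s * x[3]))
  }
})

test_that("gene selection keeps any gene significant in any contrast and cluster", {
  mk <- function(gene, cluster, contrast, p_adj)
    data.frame(gene = gene, cluster = cluster, contrast = contrast,
               p_adj = p_adj, stringsAsFactors = FALSE)
  res <- rbind(
    mk("g1", "C1", "obese vs lean", 0.20), mk("g1", "C2", "CR vs obese", 0.01),
    mk("g2", "C1", "CR vs lean",    0.04), mk("g3", "C1", "obese vs lean", 0.9),
    mk("g3", "C2", "CR vs lean",    0.6),  mk("g4", "C2", "obese vs lean", 0.049),
    mk("g5", "C1", "CR vs obese",   0.051))
  de <- list(results = res)
  expect_setequal(select_recovery_genes(de), c("g1", "g2", "g4"))
  de$results <- res[res$contrast != "CR vs obese", ]
  expect_error(select_recovery_genes(de), "CR vs obese")
})

test_that("clusters missing a condition yield NotAssessed for every gene", {
  sim <- tiny_sim()
  cells <- compute_cell_qc(sim$counts, sim$cells)
  norm <- normalize_counts(sim$counts[, cells$barcode[cells$qc_pass]])
  rtab <- build_recovery_table(norm, cells, rownames(norm)[1:20])
  c4 <- rtab[rtab$cluster == "C4", ]
  expect_true(all(c4$category == "NotAssessed"))
  expect_true(all(is.na(c4$L)))
  others <- rtab[rtab$cluster != "C4", ]
  expect_false(any(others$category == "NotAssessed"))
  # exactly one category per assessed pair
  expect_true(all(others$category %in%
                    c("Recovered", "NotRecovered", "Different")))
  expect_warning(empty <- build_recovery_table(norm, cells, character(0)),
                 "empty gene set")
  expect_equal(nrow(empty), 0)
})

test_that("category proportions are exact fractions that sum to one", {
  rtab <- data.frame(
    gene = c("g1", "g2", "g3", "g4", "g1", "g2"),
    cluster = c(rep("C1", 4), "C2", "C2"),
    L = 1, O = 2, C = 1.5,
    category = c("Recovered", "Recovered", "NotRecovered", "Different",
                 "NotAssessed", "Recovered"),
    stringsAsFactors = FALSE)
  pr <- recovery_proportions(rtab, "all_selected")
  c1 <- pr[pr$cluster == "C1", ]
  expect_equal(c(c1$Recovered, c1$NotRecovered, c1$Different),
               c(0.5, 0.25, 0.25))
  expect_equal(pr$Recovered + pr$NotRecovered + pr$Different,
               rep(1, nrow(pr)))

  # obese-DE denominator restricts to genes DE in obese vs lean per cluster
  de <- list(results = data.frame(
    gene = c("g1", "g3"), cluster = "C1", contrast = "obese vs lean",
    p_adj = c(0.01, 0.01), stringsAsFactors = FALSE))
  pr2 <- suppressWarnings(recovery_proportions(rtab, "obese_de_only", de))
  expect_equal(pr2$n_genes, 2)
  expect_equal(pr2$Recovered, 0.5)
  expect_equal(pr2$NotRecovered, 0.5)
})

test_that("cross-cluster overlap histograms match a hand tally", {
  # 6 genes x 4 clusters with a known category layout
  rtab <- expand.grid(gene = paste0("g", 1:6), cluster = paste0("C", 1:4),
                      stringsAsFactors = FALSE)
  rtab$category <- "NotRecovered"
  rtab$category[rtab$gene == "g1"] <- "Recovered"              # 4 clusters
  rtab$category[rtab$gene == "g2" & rtab$cluster %in%
                  c("C1", "C2", "C3")] <- "Recovered"          # 3 clusters
  rtab$category[rtab$gene == "g3" & rtab$cluster == "C1"] <- "Different"
  rtab$category[rtab$gene == "g4" & rtab$cluster == "C2"] <- "NotAssessed"
  h <- cluster_overlap_distribution(rtab)
  rec <- h[h$category == "Recovered", ]
  expect_equal(rec$n_genes[rec$n_clusters == 4], 1)
  expect_equal(rec$n_genes[rec$n_clusters == 3], 1)
  diffh <- h[h$category == "Different", ]
  expect_equal(diffh$n_genes, 1)
  expect_equal(diffh$n_clusters, 1)
  nr <- h[h$category == "NotRecovered", ]
  # g1 contributes nowhere; g2 once (C4); g3 3x; g4 3x; g5, g6 4x
  expect_equal(sum(nr$n_genes), 5)
  expect_equal(nr$n_genes[nr$n_clusters == 4], 2)
  expect_equal(nr$n_genes[nr$n_clusters == 3], 2)
  expect_equal(nr$n_genes[nr$n_clusters == 1], 1)
})

test_that("permuting condition labels destroys the planted structure", {
  sim <- tiny_sim()
  cells <- compute_cell_qc(sim$counts, sim$cells)
  cells <- filter_cells(cells)
  norm <- normalize_counts(sim$counts[, cells$barcode[cells$qc_pass]])
  tg <- sim$truth$genes
  pl <- tg[tg$role == "planted", ]

  rt <- build_recovery_table(norm, cells, pl$gene)
  rt <- rt[rt$category != "NotAssessed", ]
  acc <- mean(rt$category == pl$category[match(rt$gene, pl$gene)])

  withr::with_seed(99, {
    cells$condition <- sample(cells$condition)
  })
  rtp <- build_recovery_table(norm, cells, pl$gene)
  rtp <- rtp[rtp$category != "NotAssessed", ]
  accp <- mean(rtp$category == pl$category[match(rtp$gene, pl$gene)])
  expect_gt(acc, 0.8)
  expect_lt(accp, 0.6)
})
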