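test_that("small-sample Wilcoxon p-values follow the exact distribution", {
  expect_equal(wilcoxon_test(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(wilcoxon_test(c(4, 5, 6), c(1, 2, 3)), 0.1)
  expect_equal(wilcoxon_test(c(1, 2, 3), c(1, 2, 3)), 1)
  # permuting values within a group changes nothing
  a <- c(0.3, 1.7, 0.2, 2.5); b <- c(1.1, 0.9, 4.2)
  expect_identical(wilcoxon_test(a, b), wilcoxon_test(sample(a), b))
  expect_error(wilcoxon_test(numeric(0), 1), "nonempty")
})

test_that("wilcoxon_test agrees with stats::wilcox.test on both paths", {
  set.seed(11)
  for (i in 1:25) {
    na <- sample(2:12, 1); nb <- sample(2:12, 1)
    tied <- i %% 2 == 0
    pool <- if (tied) sample(1:4, na + nb, replace = TRUE) else rnorm(na + nb)
    a <- pool[seq_len(na)]; b <- pool[na + seq_len(nb)]
    exact <- min(na, nb) <= 8 && !anyDuplicated(c(a, b))
    ref <- suppressWarnings(
      stats::wilcox.test(a, b, exact = exact, correct = TRUE))$p.value
    expect_equal(wilcoxon_test(a, b), ref, tolerance = 1e-12,
                 info = paste("case", i))
  }
})

test_that("BH adjustment matches its closed examples and inflates p-values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.42), 0.42)
  set.seed(2)
  p <- runif(100)
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("condition_stats computes de-logged means and detection rates", {
  norm <- toy_counts(matrix(c(0, log(2)), 1))
  norm <- methods::as(norm, "dMatrix")
  s <- condition_stats(norm, 1:2)
  expect_equal(s$mean, 0.5)
  expect_equal(s$pct, 0.5)

  # brute-force agreement on a random matrix
  set.seed(5)
  raw <- matrix(rpois(100, 1), 10,
                dimnames = list(paste0("g", 1:10), paste0("c", 1:10)))
  raw[1, colSums(raw) == 0] <- 1
  norm2 <- normalize_counts(toy_counts(raw))
  s2 <- condition_stats(norm2, 1:10)
  for (g in 1:10) {
    expect_equal(s2$mean[g], mean(expm1(norm2[g, ])), tolerance = 1e-12)
    expect_equal(s2$pct[g], mean(norm2[g, ] > 0))
  }
  expect_error(condition_stats(norm2, integer(0)), "empty")
})

test_that("de_contrast is antisymmetric and flags unassessable contrasts", {
  sim <- tiny_sim()
  cells <- compute_cell_qc(sim$counts, sim$cells)
  norm <- normalize_counts(sim$counts[, cells$barcode[cells$qc_pass]])
  ab <- de_contrast(norm, cells, "C1", "obese", "lean")
  ba <- de_contrast(norm, cells, "C1", "lean", "obese")
  expect_equal(ab$logFC, -ba$logFC, tolerance = 1e-12)
  expect_equal(ab$p_raw, ba$p_raw, tolerance = 1e-12)
  expect_true(all(ab$p_adj >= ab$p_raw))

  # C4 is absent in lean: obese-vs-lean cannot be assessed there
  na <- de_contrast(norm, cells, "C4", "obese", "lean")
  expect_false(attr(na, "assessed"))
  expect_equal(nrow(na), 0)
  # but CR vs obese is assessable in the same cluster
  expect_true(attr(de_contrast(norm, cells, "C4", "CR", "obese"), "assessed"))
})

test_that("a gene identical across groups gets logFC 0 and p near 1", {
  # every cell has total depth 20, so normalized values depend only on counts
  de <- rep(c(1L, 9L), 10)
  m <- toy_counts(rbind(flat = rep(5L, 20), de = de, bal = 15L - de))
  cells <- data.frame(barcode = colnames(m),
                      condition = rep(c("obese", "lean"), 10),
                      cluster = "C1", qc_pass = TRUE)
  norm <- normalize_counts(m)
  r <- de_contrast(norm, cells, "C1", "obese", "lean")
  expect_equal(r$logFC[r$gene == "flat"], 0, tolerance = 1e-12)
  expect_equal(r$p_raw[r$gene == "flat"], 1)
  expect_lt(r$p_raw[r$gene == "de"], 0.01)
})

test_that("marker detection reproduces hand enumeration on a block-structured toy", {
  # 3 clusters x 20 cells; block-structured genes plus a ballast gene that
  # equalizes every cell's depth, so normalized values depend on the count
  # alone and the marker rule can be enumerated by hand:
  #   gA  expressed only in A            -> marker of A
  #   gB  expressed only in B            -> marker of B
  #   gAB expressed in A and B           -> marker of A and of B
  #   gLo expressed in 4/20 A cells      -> blocked by the 25% rule
  #   gDn absent in A, present in B, C   -> marker of B and C, never A
  #   gFl identical everywhere           -> never a marker
  #   gBal depth ballast (high in C)     -> marker of C only
  cl <- rep(c("A", "B", "C"), each = 20)
  m <- rbind(
    gA  = rep(c(9L, 0L, 0L), each = 20),
    gB  = rep(c(0L, 9L, 0L), each = 20),
    gAB = rep(c(5L, 5L, 0L), each = 20),
    gLo = c(rep(7L, 4), rep(0L, 56)),
    gDn = rep(c(0L, 4L, 4L), each = 20),
    gFl = rep(3L, 60))
  m <- rbind(m, gBal = as.integer(25L - colSums(m)))
  counts <- toy_counts(m)
  cells <- data.frame(barcode = colnames(counts), condition = "obese",
                      cluster = cl, qc_pass = TRUE)
  norm <- normalize_counts(counts)

  mk <- find_markers(norm, cells)
  expect_setequal(mk$gene[mk$cluster == "A"], c("gA", "gAB"))
  expect_setequal(mk$gene[mk$cluster == "B"], c("gB", "gAB", "gDn"))
  expect_setequal(mk$gene[mk$cluster == "C"], c("gDn", "gBal"))
  # ranked by decreasing logFC within cluster
  expect_equal(mk$logFC[mk$cluster == "B"],
               sort(mk$logFC[mk$cluster == "B"], decreasing = TRUE))

  # the detection-rate rule is inclusive: pct_in = 0.20 passes at
  # min_pct = 0.20 but is excluded at the default 0.25 regardless of fold
  loose <- find_markers(norm, cells, marker_params(min_pct = 0.20))
  expect_true("gLo" %in% loose$gene[loose$cluster == "A"])
  expect_false("gLo" %in% mk$gene[mk$cluster == "A"])
})

test_that("planted cluster markers are recovered from simulated data", {
  sim <- tiny_sim()
  res <- recovery_pipeline()
  tg <- recovery_sim()$truth$genes
  mk <- res$markers
  planted <- tg[tg$role == "marker" & tg$marker_cluster %in% mk$cluster, ]
  hit <- mapply(function(g, cl) any(mk$gene == g & mk$cluster == cl),
                planted$gene, planted$marker_cluster)
  expect_gte(mean(hit), 0.9)
})
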