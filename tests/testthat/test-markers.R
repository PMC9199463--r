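test_that("exact Wilcoxon matches hand-derived and brute-force values", {
  # fully separated groups of 3: two extreme assignments out of C(6,3)=20
  expect_equal(wilcoxonTest(c(1, 2, 3), c(4, 5, 6), mode = "exact")$p, 0.1)
  # all values tied: p = 1 by the zero-variance convention
  expect_equal(wilcoxonTest(c(5, 5), c(5, 5), mode = "exact")$p, 1)
  expect_equal(wilcoxonTest(c(5, 5), c(5, 5), mode = "normal")$p, 1)
  expect_error(wilcoxonTest(numeric(0), 1), "non-empty")
  set.seed(20)
  for (rep in 1:10) {
    x <- sample(0:5, 6, replace = TRUE) + rnorm(6, 0, 1e-6)
    y <- sample(0:5, 6, replace = TRUE) + rnorm(6, 0, 1e-6)
    expect_equal(wilcoxonTest(x, y, mode = "exact")$p, bruteWilcoxP(x, y))
  }
})

test_that("normal-mode p agrees with exact within 0.02 at n = m = 6", {
  set.seed(21)
  for (rep in 1:20) {
    x <- rnorm(6)
    y <- rnorm(6, mean = sample(c(0, 1), 1))
    pe <- wilcoxonTest(x, y, mode = "exact")$p
    pn <- wilcoxonTest(x, y, mode = "normal")$p
    expect_lt(abs(pe - pn), 0.02)
  }
})

test_that("normal mode reproduces the reference tie-corrected approximation", {
  set.seed(22)
  for (rep in 1:20) {
    x <- rnorm(15)
    y <- rnorm(20, 0.5)
    ours <- wilcoxonTest(x, y, mode = "normal")$p
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = TRUE))$p.value
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("BH adjustment matches step-up arithmetic and the reference", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.3), 0.3)
  expect_equal(bhAdjust(c(0.005, 0.1)), c(0.01, 0.1))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(23)
  p <- runif(50)
  expect_equal(bhAdjust(p), p.adjust(p, "BH"), tolerance = 1e-12)
  # permutation invariance and monotonicity
  perm <- sample(50)
  expect_equal(bhAdjust(p)[perm], bhAdjust(p[perm]), tolerance = 1e-12)
  p2 <- p
  p2[7] <- p2[7] / 2
  expect_true(all(bhAdjust(p2) <= bhAdjust(p) + 1e-12))
})

test_that("pct3 equals the per-cluster double-loop oracle", {
  set.seed(24)
  for (rep in 1:5) {
    m <- randomCounts(15, 40, seed = rep, density = 0.4)
    labels <- sample(0:3, 40, replace = TRUE)
    enriched <- 0L
    got <- pct3PerGene(m, labels, enriched)
    d <- as.matrix(m)
    for (gi in seq_len(nrow(d))) {
      fracs <- c()
      for (c in setdiff(sort(unique(labels)), enriched)) {
        cells <- which(labels == c)
        fracs <- c(fracs, sum(d[gi, cells] > 0) / length(cells))
      }
      expect_identical(unname(got[gi]), max(fracs))
    }
  }
  expect_error(pct3PerGene(randomCounts(3, 4), rep(0L, 4), 0L), "undefined")
  # gene all-zero outside enriched clusters -> 0
  m <- randomCounts(5, 10, seed = 1)
  m[2, 6:10] <- 0
  expect_equal(unname(pct3PerGene(m, rep(c(0L, 1L), each = 5), 0L)[2]), 0)
})

test_that("marker selection thresholds are strict", {
  base <- data.frame(gene = "g", avg_log2fc = 1, p = 0.01, p_adj = 0.04,
                     pct1 = 0.85, pct2 = 0.03, pct3 = 0.09,
                     selected = FALSE, high_specificity = FALSE)
  expect_true(selectMarkers(base)$selected)
  expect_true(selectMarkers(base)$high_specificity)
  atBoundary <- transform(base, pct1 = 0.80)
  expect_false(selectMarkers(atBoundary)$selected)   # "more than 80%" strict
  atAlpha <- transform(base, p_adj = 0.05)
  expect_false(selectMarkers(atAlpha)$selected)
  atPct3 <- transform(base, pct3 = 0.10)
  expect_false(selectMarkers(atPct3)$high_specificity)
  expect_true(selectMarkers(atPct3)$selected)
})

test_that("the DE table reports null genes, pct fractions and planted markers", {
  cfg <- tinySimConfig(seed = 77L, nCells = 300L)
  sce <- logNormalize(simulateTissueCounts(cfg, "lung"))
  lab <- as.integer(factor(colData(sce)$cellType)) - 1L
  peri <- which(levels(factor(colData(sce)$cellType)) == "pericyte") - 1L
  counts <- assay(sce, "counts")
  mask <- as.vector(counts["Cspg4", ] > 0 & counts["Pdgfrb", ] > 0) &
    lab == peri
  tab <- computeMarkerTable(sce, mask, lab, enriched = peri)
  expect_true(all(tab$pct1 >= 0 & tab$pct1 <= 1))
  expect_true(all(tab$p_adj >= tab$p - 1e-12))
  # planted markers are selected with near-total pct1 and tiny pct2
  planted <- metadata(sce)$truth$plantedMarkers
  sel <- tab[tab$gene %in% planted, ]
  expect_true(all(sel$selected))
  expect_true(all(sel$p_adj < 0.05))
  # decoys (detected in ~50% of stringent pericytes) are never selected
  decoys <- intersect(metadata(sce)$truth$decoyMarkers, tab$gene)
  expect_false(any(tab[tab$gene %in% decoys, "selected"]))
})

test_that("a gene identical in both groups gets p ~ 1 and zero fold change", {
  m <- randomCounts(10, 30, seed = 25L)
  m[4, ] <- 2L                       # identical everywhere
  # equalize library sizes so identical counts mean identical expression
  libs <- Matrix::colSums(m)
  filler <- max(libs) - libs + 1
  m <- rbind(m, Matrix::Matrix(filler, nrow = 1, sparse = TRUE,
                               dimnames = list("filler", colnames(m))))
  sce <- countsToSce(as(m, "CsparseMatrix"))
  sce <- logNormalize(sce)
  mask <- rep(c(TRUE, FALSE), 15)
  tab <- computeMarkerTable(sce, mask, rep(c(0L, 1L), each = 15), 0L)
  row <- tab[tab$gene == rownames(m)[4], ]
  expect_equal(row$avg_log2fc, 0, tolerance = 1e-9)
  expect_gt(row$p, 0.9)
})

test_that("pct1 counts expressing stringent cells from raw counts", {
  m <- randomCounts(4, 10, seed = 26L, density = 0.9)
  m[1, ] <- c(1L, 2L, 0L, 3L, 1L, 0L, 0L, 0L, 0L, 0L)
  sce <- logNormalize(countsToSce(m))
  mask <- c(rep(TRUE, 5), rep(FALSE, 5))
  tab <- computeMarkerTable(sce, mask, rep(c(0L, 1L), each = 5), 0L)
  expect_equal(unname(tab[tab$gene == rownames(m)[1], "pct1"]), 0.8) # 4 of 5
})

test_that("the cross-tissue Venn assigns genes to their membership patterns", {
  sets <- list(
    lung = c("Kcnk3", "Higd1b", "Cox4i2", "Gucy1a3"),
    heart = c("Rgs4", "Higd1b", "Gm13889"),
    kidney = c("Myh11", "Kcna5", "Cox4i2", "Gm13889", "Gucy1a3", "Pcp4l1"),
    bladder = c("Pcp4l1", "Cox4i2"))
  venn <- crossTissueVenn(sets)
  row <- function(pat) venn$genes[venn$pattern == pat]
  expect_match(row("lung+heart"), "Higd1b")
  expect_match(row("lung+kidney+bladder"), "Cox4i2")
  expect_match(row("kidney+bladder"), "Pcp4l1")
  # conservation: pattern sizes sum to the union size
  expect_equal(sum(venn$n), length(unique(unlist(sets))))
  # disjoint sets give only singleton patterns
  disj <- crossTissueVenn(list(a = c("x", "y"), b = c("z")))
  expect_setequal(disj$pattern, c("a", "b"))
  expect_equal(sum(disj$n), 3)
  expect_error(crossTissueVenn(list(a = "x")), "at least 2")
})

test_that("Wilcoxon is calibrated under the negative-binomial null", {
  set.seed(27)
  R <- 2000
  pvals <- vapply(seq_len(R), function(i) {
    x <- rnbinom(40, mu = 2, size = 2)
    y <- rnbinom(60, mu = 2, size = 2)
    wilcoxonTest(x, y, mode = "normal")$p
  }, 0)
  rate <- mean(pvals < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / R))
})
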