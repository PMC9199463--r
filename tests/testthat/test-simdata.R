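test_that("simulation is bit-identical under a fixed seed", {
  cfg <- tinySimConfig(seed = 21L)
  a <- simulateTissueCounts(cfg, "lung")
  b <- simulateTissueCounts(cfg, "lung")
  expect_identical(assay(a, "counts"), assay(b, "counts"))
  expect_identical(colData(a)$cellType, colData(b)$cellType)
  m1 <- simulateMultiTissue(cfg)
  m2 <- simulateMultiTissue(cfg)
  for (t in names(m1))
    expect_identical(assay(m1[[t]], "counts"), assay(m2[[t]], "counts"))
})

test_that("counts are non-negative integers with positive library sizes", {
  cfg <- tinySimConfig(seed = 5L)
  sce <- simulateTissueCounts(cfg, "heart")
  x <- assay(sce, "counts")@x
  expect_true(all(x >= 0))
  expect_true(all(x == round(x)))
  expect_true(all(Matrix::colSums(assay(sce, "counts")) > 0))
})

test_that("empirical planted-marker detection matches piIn in pericytes", {
  # ~500 pericytes so the binomial standard error is about 0.01
  cfg <- simConfig(nTissues = 1L, nCells = 1000L, nGenes = 300L,
                   cellTypeProportions = c(pericyte = 0.5, smooth_muscle = 0.1,
                                           fibroblast = 0.15,
                                           endothelial = 0.15, other = 0.1),
                   nPlantedMarkersPerTissue = 6L, nSharedMarkers = 0L,
                   piIn = 0.95, piOut = 0.01, seed = 31L)
  sce <- simulateTissueCounts(cfg, "lung")
  peri <- colData(sce)$isPericyte
  expect_gt(sum(peri), 400)
  planted <- metadata(sce)$truth$plantedMarkers
  det <- Matrix::rowMeans(assay(sce, "counts")[planted, peri, drop = FALSE] > 0)
  expect_true(all(abs(det - 0.95) <= 0.03))
  # leak converges to piOut within 3 binomial standard errors
  leak <- Matrix::rowMeans(assay(sce, "counts")[planted, !peri, drop = FALSE] > 0)
  se <- sqrt(0.01 * 0.99 / sum(!peri))
  expect_true(all(abs(leak - 0.01) <= 3 * se + 1e-9))
})

test_that("piOut = 0 gives planted markers zero counts outside pericytes", {
  cfg <- tinySimConfig(seed = 7L, piOut = 0)
  sce <- simulateTissueCounts(cfg, "lung")
  peri <- colData(sce)$isPericyte
  planted <- metadata(sce)$truth$plantedMarkers
  sub <- assay(sce, "counts")[planted, !peri, drop = FALSE]
  expect_identical(sum(sub), 0)
})

test_that("shared markers are planted in exactly their member tissues", {
  cfg <- simConfig(nTissues = 4L, nCells = 400L, nGenes = 600L,
                   nSharedMarkers = 1L, piIn = 0.95, piOut = 0, seed = 13L)
  sims <- simulateMultiTissue(cfg)
  membership <- metadata(sims$lung)$truth$sharedMarkers[["mkshared_01"]]
  expect_setequal(membership, c("lung", "heart"))
  for (t in names(sims)) {
    sce <- sims[[t]]
    peri <- colData(sce)$isPericyte
    frac <- mean(assay(sce, "counts")["mkshared_01", peri] > 0)
    if (t %in% membership) expect_gt(frac, 0.8) else expect_equal(frac, 0)
  }
})

test_that("per-tissue planted marker sets are disjoint and in-universe", {
  cfg <- tinySimConfig(seed = 9L)
  sims <- simulateMultiTissue(cfg)
  sets <- lapply(sims, function(s) metadata(s)$truth$plantedMarkers)
  expect_length(intersect(sets[[1]], sets[[2]]), 0)
  for (t in names(sims))
    expect_true(all(sets[[t]] %in% rownames(sims[[t]])))
})

test_that("invalid cell-type proportions are rejected", {
  expect_error(simConfig(cellTypeProportions = c(pericyte = 0.5, smooth_muscle = 0.2,
                                                 fibroblast = 0.2,
                                                 endothelial = 0.2, other = 0.2)),
               "sum")
  expect_error(simConfig(piIn = 0.1, piOut = 0.2), "piIn")
})

test_that("spatial section partitions the grid and plants connected arteries", {
  cfg <- tinySimConfig(seed = 17L)
  spots <- simulateSpatialSection(cfg, grid = c(24, 24), seed = 41L)
  region <- colData(spots)$region
  expect_length(region, 24 * 24)
  expect_true(all(region %in% c("artery", "capillary", "pericyte", "background")))
  paths <- metadata(spots)$arteryPaths
  expect_gt(length(paths), 0)
  for (p in paths) {
    steps <- abs(diff(p[, 1])) + abs(diff(p[, 2]))
    expect_true(all(steps == 1))          # 4-connected consecutive spots
    expect_false(anyDuplicated(paste(p[, 1], p[, 2])) > 0)  # self-avoiding
  }
  # determinism
  spots2 <- simulateSpatialSection(cfg, grid = c(24, 24), seed = 41L)
  expect_identical(assay(spots, "counts"), assay(spots2, "counts"))
})

test_that("spatial marker expression follows the planted regions", {
  cfg <- tinySimConfig(seed = 19L)
  none <- simulateSpatialSection(cfg, grid = c(16, 16), seed = 3L,
                                 nArteryPaths = 0L)
  expect_length(spotSets(none, "Myh11"), 0)
  full <- simulateSpatialSection(cfg, grid = c(16, 16), seed = 3L,
                                 coexprProb = 1)
  peri <- colnames(full)[colData(full)$region == "pericyte"]
  counts <- assay(full, "counts")
  expect_true(all(counts["Cspg4", peri] > 0 & counts["Pdgfrb", peri] > 0))
  # artery marker probability 1 recovers exactly the planted path spots
  art <- simulateSpatialSection(cfg, grid = c(16, 16), seed = 3L,
                                arteryProb = 1)
  expect_setequal(spotSets(art, "Myh11"),
                  colnames(art)[colData(art)$region == "artery"])
})

test_that("too-small grids are rejected", {
  cfg <- tinySimConfig()
  expect_error(simulateSpatialSection(cfg, grid = c(6, 20)), "at least 8")
})
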