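# Gene-universe layout shared by all tissues of one configuration.
# Planted/shared/decoy/program gene names are deterministic functions of the
# configuration, so every tissue draws from the same universe.
buildSimLayout <- function(config) {
  tissues <- config@tissueNames
  types <- names(config@cellTypeProportions)
  planted <- lapply(tissues, function(t)
    sprintf("mk_%s_%02d", t, seq_len(config@nPlantedMarkersPerTissue)))
  names(planted) <- tissues
  shared <- character(0)
  sharedMembership <- list()
  if (config@nSharedMarkers > 0L) {
    shared <- sprintf("mkshared_%02d", seq_len(config@nSharedMarkers))
    subsets <- if (length(tissues) >= 2L)
      utils::combn(tissues, 2L, simplify = FALSE) else list(tissues)
    sharedMembership <- lapply(seq_len(config@nSharedMarkers), function(i)
      subsets[[(i - 1L) %% length(subsets) + 1L]])
    names(sharedMembership) <- shared
  }
  decoys <- lapply(tissues, function(t)
    sprintf("decoy_%s_%02d", t, seq_len(config@nDecoysPerTissue)))
  names(decoys) <- tissues
  nProg <- 30L
  program <- lapply(types, function(ty) sprintf("prog_%s_%02d", ty, seq_len(nProg)))
  names(program) <- types
  spatialAnalogs <- setdiff(c("Myh11", "Pecam1", "Higd1b", "Notch3"),
                            config@canonicalPair)
  named <- c(config@canonicalPair, spatialAnalogs, unlist(planted), shared,
             unlist(decoys), unlist(program))
  if (anyDuplicated(named))
    stopf("gene-universe name collision in the simulation layout")
  nBg <- config@nGenes - length(named)
  if (nBg < 10L)
    stopf("nGenes (%d) too small for the layout: need at least %d genes",
          config@nGenes, length(named) + 10L)
  background <- sprintf("g%04d", seq_len(nBg))
  list(genes = c(named, background), planted = planted,
       sharedMembership = sharedMembership, decoys = decoys,
       program = program, background = background,
       spatialAnalogs = spatialAnalogs)
}

# On-state counts: 1 + NB(mu - 1, size). The unit shift guarantees
# P(count > 0 | gated on) = 1, so Bernoulli gates control the expressing
# fraction exactly.
rOnCounts <- function(n, mu, size) {
  if (n == 0L) return(integer(0))
  1L + stats::rnbinom(n, mu = max(mu - 1, 0.01), size = size)
}

# Gated marker row: on-probability per cell, shifted-NB counts when on.
gatedRow <- function(onProb, mu, size, lib) {
  n <- length(onProb)
  gate <- stats::runif(n) < onProb
  out <- integer(n)
  out[gate] <- rOnCounts(sum(gate), mu, size) # library factor deliberately
  out                                         # absent: the gate IS the signal
}

#' Simulate one tissue's single-cell counts with ground truth
#'
#' Cells are assigned to the configured cell types; each cell type expresses
#' a private program of genes (negative binomial on a cell-type mean times a
#' lognormal library factor), which makes the populations separable in PC
#' space. Pericytes carry both canonical markers with probability
#' `dualPosRate` (otherwise one of the two at random); smooth-muscle cells
#' carry only the second canonical marker (probability 0.8), forming the
#' confusable mural population. Planted tissue-specific markers are detected
#' (count > 0) with probability `piIn` in pericytes of their target tissue
#' and `piOut` elsewhere; decoys use `decoyPiIn` in pericytes. On-state
#' counts are drawn from a unit-shifted negative binomial so the gates
#' control expression fractions exactly. Deterministic given `seed`.
#'
#' @param config A [SimConfig-class].
#' @param tissueId Tissue label; must be one of `config@tissueNames`.
#' @param seed Integer seed (default: derived from the config seed and the
#'   tissue label).
#' @return A `SingleCellExperiment` (genes x cells, `counts` assay) with
#'   `colData` columns `tissue`, `cellType`, `isPericyte` and
#'   `metadata()$truth` holding `plantedMarkers`, `sharedMarkers` (gene ->
#'   tissue membership), `decoyMarkers`, `canonicalPair` and `programGenes`.
#' @export
simulateTissueCounts <- function(config, tissueId,
                                 seed = deriveSeed(config@seed, tissueId)) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  if (!tissueId %in% config@tissueNames)
    stopf("unknown tissue '%s' (configured: %s)", tissueId,
          paste(config@tissueNames, collapse = ", "))
  layout <- buildSimLayout(config)
  tIdx <- match(tissueId, config@tissueNames)
  nCells <- if (length(config@nCells) == 1L) config@nCells else
    config@nCells[tIdx]
  size <- config@nbDispersion
  props <- config@cellTypeProportions
  withSeed(seed, {
    cellType <- sample(names(props), nCells, replace = TRUE, prob = props)
    lib <- stats::rlnorm(nCells, config@libsizeLognormal[1],
                         config@libsizeLognormal[2])
    isPeri <- cellType == "pericyte"
    isSm <- cellType == "smooth_muscle"
    genes <- layout$genes
    counts <- matrix(0L, length(genes), nCells,
                     dimnames = list(genes, sprintf("%s_cell%05d", tissueId,
                                                    seq_len(nCells))))
    # background genes: gene-level lognormal-ish means, NB counts
    bg <- layout$background
    baseMu <- stats::rgamma(length(bg), shape = 0.8, rate = 2)
    counts[bg, ] <- matrix(
      stats::rnbinom(length(bg) * nCells,
                     mu = outer(baseMu, lib), size = size),
      length(bg), nCells)
    # cell-type programs
    for (ty in names(layout$program)) {
      pg <- layout$program[[ty]]
      mu <- ifelse(rep(cellType == ty, each = length(pg)), 3, 0.05)
      counts[pg, ] <- matrix(
        stats::rnbinom(length(pg) * nCells, mu = mu * rep(lib, each = length(pg)),
                       size = size),
        length(pg), nCells)
    }
    # canonical pair
    ca <- config@canonicalPair[1]
    cb <- config@canonicalPair[2]
    bothOn <- isPeri & stats::runif(nCells) < config@dualPosRate
    singlePick <- stats::runif(nCells) < 0.5     # which marker when not dual
    aOn <- bothOn | (isPeri & !bothOn & singlePick)
    bOn <- bothOn | (isPeri & !bothOn & !singlePick)
    aOn <- aOn | (!isPeri & stats::runif(nCells) < config@piOut)
    bOn <- bOn | (!isPeri & !isSm & stats::runif(nCells) < config@piOut)
    bOn <- bOn | (isSm & stats::runif(nCells) < 0.8)
    counts[ca, aOn] <- rOnCounts(sum(aOn), 3, size)
    counts[cb, bOn] <- rOnCounts(sum(bOn), 3, size)
    # smooth-muscle / endothelial analog markers (spatial gene universe)
    for (sp in layout$spatialAnalogs) {
      onProb <- rep(config@piOut, nCells)
      if (sp == "Myh11") onProb[isSm] <- 0.6
      if (sp == "Pecam1") onProb[cellType == "endothelial"] <- 0.8
      counts[sp, ] <- gatedRow(onProb, 3, size, lib)
    }
    # planted tissue-specific markers (all tissues' sets live in the universe)
    for (t in config@tissueNames) {
      for (g in layout$planted[[t]]) {
        onProb <- rep(config@piOut, nCells)
        if (t == tissueId) onProb[isPeri] <- config@piIn
        counts[g, ] <- gatedRow(onProb, 4, size, lib)
      }
    }
    # shared markers: piIn in pericytes of member tissues
    for (g in names(layout$sharedMembership)) {
      onProb <- rep(config@piOut, nCells)
      if (tissueId %in% layout$sharedMembership[[g]])
        onProb[isPeri] <- config@piIn
      counts[g, ] <- gatedRow(onProb, 4, size, lib)
    }
    # decoys: decoyPiIn in pericytes of their tissue
    for (t in config@tissueNames) {
      for (g in layout$decoys[[t]]) {
        onProb <- rep(config@piOut, nCells)
        if (t == tissueId) onProb[isPeri] <- config@decoyPiIn
        counts[g, ] <- gatedRow(onProb, 4, size, lib)
      }
    }
    # guard: no zero-library cells (degenerate only at tiny gene universes)
    zero <- colSums(counts) == 0
    if (any(zero)) counts[layout$background[1], zero] <- 1L
    sce <- SingleCellExperiment(
      assays = list(counts = as(counts, "CsparseMatrix")),
      colData = DataFrame(tissue = rep(tissueId, nCells),
                          cellType = cellType, isPericyte = isPeri,
                          row.names = colnames(counts)))
    metadata(sce)$truth <- list(
      plantedMarkers = layout$planted[[tissueId]],
      sharedMarkers = layout$sharedMembership,
      decoyMarkers = layout$decoys[[tissueId]],
      canonicalPair = config@canonicalPair,
      programGenes = layout$program)
    metadata(sce)$seed <- seed
    sce
  })
}

#' Simulate a multi-tissue single-cell study
#'
#' One count matrix per configured tissue over a shared gene universe.
#' Shared markers are planted in their designated tissue subsets (membership
#' recorded in each tissue's truth metadata). Per-tissue seeds are derived
#' reproducibly from the master seed and the tissue label, so tissues are
#' independent yet the whole study is reproducible.
#'
#' @param config A [SimConfig-class] with `nTissues >= 2`.
#' @param seed Master seed (default `config@seed`).
#' @return Named list (tissue -> `SingleCellExperiment`).
#' @export
simulateMultiTissue <- function(config, seed = config@seed) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  if (config@nTissues < 2L)
    stopf("multi-tissue simulation needs nTissues >= 2")
  out <- lapply(config@tissueNames, function(t)
    simulateTissueCounts(config, t, seed = deriveSeed(seed, t)))
  names(out) <- config@tissueNames
  out
}

#' Simulate a spatial section with vessel-like arteries
#'
#' Lays out an H x W spot grid: artery spots form 1-wide self-avoiding
#' 4-connected paths (each consecutive pair at Manhattan distance 1)
#' expressing the smooth-muscle marker; capillary spots are scattered at
#' random expressing the endothelial marker; pericyte spots are placed
#' adjacent to capillary spots and co-express the canonical pair plus the
#' Higd1b/Notch3 analogs with the stated probabilities; remaining spots are
#' background. Region marker genes are expressed only in their own region
#' (low uniform background noise comes from a separate housekeeping block),
#' and each region carries a private expression program so spot clustering
#' can recover it. Region labels partition the grid.
#'
#' @param config A [SimConfig-class] (supplies the canonical pair, dispersion
#'   and dual-positive rate).
#' @param grid `c(H, W)`, both at least 8.
#' @param seed Integer seed.
#' @param nArteryPaths Number of artery paths (default 2; 0 for none).
#' @param capillaryFraction Fraction of spots made capillary (default 0.12).
#' @param pericyteAdjacencyProb Probability a capillary spot seeds an
#'   adjacent pericyte spot (default 0.6).
#' @param arteryProb,capillaryProb Expression probability of the artery
#'   (Myh11) and capillary (Pecam1) markers in their spots (default 0.95).
#' @param coexprProb Probability a pericyte spot expresses both canonical
#'   markers (default `config@dualPosRate`).
#' @param higd1bProb,notch3Prob Expression probabilities of the two pericyte
#'   co-localization markers in pericyte spots (defaults 0.75, 0.7).
#' @return A `SingleCellExperiment` (genes x spots) with `colData` columns
#'   `row`, `col`, `region` and `metadata()$arteryPaths` (list of coordinate
#'   matrices).
#' @export
simulateSpatialSection <- function(config, grid, seed = config@seed,
                                   nArteryPaths = 2L,
                                   capillaryFraction = 0.12,
                                   pericyteAdjacencyProb = 0.6,
                                   arteryProb = 0.95, capillaryProb = 0.95,
                                   coexprProb = config@dualPosRate,
                                   higd1bProb = 0.75, notch3Prob = 0.7) {
  stopifnot(is(config, "SimConfig"))
  H <- as.integer(grid[1])
  W <- as.integer(grid[2])
  if (H < 8L || W < 8L) stopf("grid must be at least 8 x 8 (got %d x %d)", H, W)
  size <- config@nbDispersion
  withSeed(seed, {
    region <- matrix("background", H, W)
    paths <- list()
    if (nArteryPaths > 0L) {
      for (k in seq_len(nArteryPaths)) {
        path <- NULL
        for (attempt in 1:25) {
          path <- arteryWalk(H, W, region, targetLen = round(0.8 * max(H, W)))
          if (!is.null(path) && nrow(path) >= 5L) break
          path <- NULL
        }
        if (is.null(path))
          stopf("could not place artery path %d on a %d x %d grid", k, H, W)
        region[path] <- "artery"
        paths[[k]] <- path
      }
    }
    free <- which(region == "background")
    nCap <- min(length(free), round(capillaryFraction * H * W))
    cap <- sample(free, nCap)
    region[cap] <- "capillary"
    capIdx <- which(region == "capillary", arr.ind = TRUE)
    for (r in sample(seq_len(nrow(capIdx)))) {
      if (stats::runif(1) >= pericyteAdjacencyProb) next
      nb <- neighbors4(capIdx[r, 1], capIdx[r, 2], H, W)
      open <- nb[region[nb] == "background", , drop = FALSE]
      if (nrow(open)) {
        pick <- open[sample.int(nrow(open), 1L), , drop = FALSE]
        region[pick] <- "pericyte"
      }
    }
    regVec <- as.vector(region)
    rows <- rep(seq_len(H), times = W)
    cols <- rep(seq_len(W), each = H)
    barcodes <- sprintf("spot_r%03d_c%03d", rows, cols)
    nSpots <- H * W
    ca <- config@canonicalPair[1]
    cb <- config@canonicalPair[2]
    markers <- unique(c("Myh11", "Pecam1", ca, cb, "Higd1b", "Notch3"))
    regions <- c("artery", "capillary", "pericyte", "background")
    prog <- lapply(regions, function(rg) sprintf("sprog_%s_%02d", rg, 1:20))
    names(prog) <- regions
    bg <- sprintf("sbg%03d", 1:120)
    genes <- c(markers, unlist(prog), bg)
    counts <- matrix(0L, length(genes), nSpots,
                     dimnames = list(genes, barcodes))
    counts[bg, ] <- matrix(stats::rnbinom(length(bg) * nSpots, mu = 0.3,
                                          size = size),
                           length(bg), nSpots)
    for (rg in regions) {
      mu <- ifelse(rep(regVec == rg, each = 20L), 4, 0.05)
      counts[prog[[rg]], ] <- matrix(
        stats::rnbinom(20L * nSpots, mu = mu, size = size), 20L, nSpots)
    }
    gateRow <- function(gene, prob, inRegion, mu = 3) {
      on <- regVec %in% inRegion & stats::runif(nSpots) < prob
      counts[gene, on] <<- rOnCounts(sum(on), mu, size)
    }
    gateRow("Myh11", arteryProb, "artery")
    gateRow("Pecam1", capillaryProb, "capillary")
    both <- regVec == "pericyte" & stats::runif(nSpots) < coexprProb
    counts[ca, both] <- rOnCounts(sum(both), 3, size)
    counts[cb, both] <- rOnCounts(sum(both), 3, size)
    gateRow("Higd1b", higd1bProb, "pericyte")
    gateRow("Notch3", notch3Prob, "pericyte")
    sce <- SingleCellExperiment(
      assays = list(counts = as(counts, "CsparseMatrix")),
      colData = DataFrame(row = rows, col = cols, region = regVec,
                          row.names = barcodes))
    metadata(sce)$arteryPaths <- paths
    metadata(sce)$seed <- seed
    sce
  })
}

neighbors4 <- function(r, c, H, W) {
  nb <- rbind(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L))
  nb[nb[, 1] >= 1L & nb[, 1] <= H & nb[, 2] >= 1L & nb[, 2] <= W, ,
     drop = FALSE]
}

# Self-avoiding 4-connected walk over free grid spots, preferring to continue
# straight; returns a 2-column coordinate matrix or NULL when stuck early.
arteryWalk <- function(H, W, region, targetLen) {
  starts <- rbind(cbind(1L, sample.int(W, 1L)),
                  cbind(H, sample.int(W, 1L)),
                  cbind(sample.int(H, 1L), 1L),
                  cbind(sample.int(H, 1L), W))
  cur <- starts[sample.int(4L, 1L), , drop = FALSE]
  if (region[cur] != "background") return(NULL)
  path <- cur
  lastDir <- NULL
  for (step in seq_len(targetLen - 1L)) {
    nb <- neighbors4(path[nrow(path), 1], path[nrow(path), 2], H, W)
    onPath <- paste(nb[, 1], nb[, 2]) %in% paste(path[, 1], path[, 2])
    ok <- !onPath & region[nb] == "background"
    nb <- nb[ok, , drop = FALSE]
    if (!nrow(nb)) break
    w <- rep(1, nrow(nb))
    if (!is.null(lastDir)) {
      straight <- nb[, 1] == path[nrow(path), 1] + lastDir[1] &
        nb[, 2] == path[nrow(path), 2] + lastDir[2]
      w[straight] <- 4
    }
    pick <- nb[sample.int(nrow(nb), 1L, prob = w), , drop = FALSE]
    lastDir <- c(pick[1, 1] - path[nrow(path), 1],
                 pick[1, 2] - path[nrow(path), 2])
    path <- rbind(path, pick)
  }
  path
}
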