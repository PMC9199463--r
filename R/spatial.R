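#' Cluster spatial spots
#'
#' Runs the single-cell pipeline stages on the spot x gene matrix:
#' log-normalization, VST selection of variable genes, PCA, k-nearest
#' neighbors, shared-nearest-neighbor Jaccard graph and Louvain clustering.
#'
#' @param spots `SingleCellExperiment` of genes x spots counts (a
#'   [simulateSpatialSection()] result or a read bundle).
#' @param nHvg Number of variable genes (default 500, capped at the
#'   universe).
#' @param nPcs Number of principal components (default 10).
#' @param k Neighborhood size (default 20).
#' @param prune SNN pruning threshold (default 1/15).
#' @param resolution Louvain resolution (default 0.5).
#' @param seed Seed for the Louvain sweep order.
#' @param scaleFactor Normalization scale factor (default 10,000).
#' @return Integer 0-based cluster labels per spot (attributes as in
#'   [louvainCluster()]).
#' @export
clusterSpots <- function(spots, nHvg = 500, nPcs = 10, k = 20,
                         prune = 1 / 15, resolution = 0.5, seed = 0L,
                         scaleFactor = 1e4) {
  if (ncol(spots) < 2L) stopf("need at least 2 spots")
  spots <- logNormalize(spots, scaleFactor)
  hvgs <- suppressWarnings(selectHvgVst(spots, min(nHvg, nrow(spots))))
  nPcs <- min(nPcs, length(hvgs) - 1L, ncol(spots) - 1L)
  emb <- scaleAndPca(spots, hvgs, nPcs)
  nbrs <- knnNeighbors(emb, min(k, ncol(spots) - 1L))
  g <- snnJaccard(nbrs, prune)
  louvainCluster(g, resolution, seed)
}

#' Designate pericyte spots at cluster level
#'
#' Applies the dual-positive-fraction enrichment rule of
#' [findEnrichedClusters()] to spot clusters and returns all spots of the
#' qualifying clusters (entire clusters are designated, pooling multiple
#' qualifying clusters).
#'
#' @param spots `SingleCellExperiment` of genes x spots counts.
#' @param labels Integer spot cluster labels.
#' @param params A [GateParams-class] naming the two canonical markers.
#' @return Character vector of designated spot barcodes (possibly empty,
#'   with a warning).
#' @export
designatePericyteSpots <- function(spots, labels, params = gateParams()) {
  enriched <- findEnrichedClusters(spots, labels, params)
  if (!length(enriched)) return(character(0))
  colnames(spots)[labels %in% enriched]
}

#' Spots expressing a gene
#'
#' @param spots `SingleCellExperiment` of genes x spots counts.
#' @param gene Gene ID; must exist in the universe.
#' @return Character vector of barcodes of spots with count > 0.
#' @export
spotSets <- function(spots, gene) {
  counts <- if (is(spots, "SummarizedExperiment")) assay(spots, "counts")
    else spots
  if (!gene %in% rownames(counts))
    stopf("gene '%s' absent from the spot gene universe", gene)
  colnames(counts)[as.vector(counts[gene, ] > 0)]
}

#' Three-set co-localization Venn
#'
#' Partitions the union of two per-gene spot sets A and B and the
#' cluster-designated pericyte spot set P into its seven regions and reports
#' overlap percentages with |P| as the explicit denominator (see
#' [VennColocalization-class]).
#'
#' @param setA,setB Character vectors of spot barcodes (e.g. [spotSets()]
#'   results).
#' @param pericyteSpots Character vector of designated pericyte spots.
#' @return A [VennColocalization-class].
#' @export
vennColocalize <- function(setA, setB, pericyteSpots) {
  a <- unique(setA)
  b <- unique(setB)
  p <- unique(pericyteSpots)
  inA <- function(x) x %in% a
  inB <- function(x) x %in% b
  inP <- function(x) x %in% p
  u <- unique(c(a, b, p))
  regions <- c(
    A_only  = sum(inA(u) & !inB(u) & !inP(u)),
    B_only  = sum(!inA(u) & inB(u) & !inP(u)),
    P_only  = sum(!inA(u) & !inB(u) & inP(u)),
    AB_only = sum(inA(u) & inB(u) & !inP(u)),
    AP_only = sum(inA(u) & !inB(u) & inP(u)),
    BP_only = sum(!inA(u) & inB(u) & inP(u)),
    ABP     = sum(inA(u) & inB(u) & inP(u)))
  nP <- length(p)
  pct <- if (nP > 0) c(
    pct_overlap_A = 100 * sum(inA(p)) / nP,
    pct_overlap_B = 100 * sum(inB(p)) / nP,
    pct_both_in_P = 100 * sum(inA(p) & inB(p)) / nP)
  else c(pct_overlap_A = NA_real_, pct_overlap_B = NA_real_,
         pct_both_in_P = NA_real_)
  new("VennColocalization", regionSizes = as.numeric2(regions),
      percentages = pct,
      setSizes = c(A = length(a), B = length(b), P = nP))
}

as.numeric2 <- function(x) stats::setNames(as.numeric(x), names(x))
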