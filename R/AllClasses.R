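#' @importClassesFrom Matrix dgCMatrix
NULL

# ---------------------------------------------------------------------------
# SimConfig
# ---------------------------------------------------------------------------

#' Simulation configuration
#'
#' Parameters of the synthetic multi-tissue single-cell study. The generator
#' emulates the statistical structure the marker-discovery pipeline assumes:
#' each tissue holds a pericyte population co-expressing two canonical mural
#' markers, a smooth-muscle population expressing only one of them (the
#' confusable mural population), fibroblast/endothelial/other backgrounds,
#' planted tissue-specific marker genes with controlled detection
#' probabilities, shared markers planted in designated tissue subsets, and
#' decoy markers whose in-population detection sits below the pct1 selection
#' threshold.
#'
#' @slot nTissues Number of tissues (>= 1; multi-tissue simulation needs >= 2).
#' @slot tissueNames Tissue labels, length `nTissues`.
#' @slot nCells Cells per tissue (length 1 or `nTissues`).
#' @slot nGenes Size of the shared gene universe.
#' @slot cellTypeProportions Named fractions over cell types; must contain
#'   `pericyte`, `smooth_muscle`, `fibroblast`, `endothelial`, `other` and
#'   sum to 1 (tolerance 1e-9).
#' @slot canonicalPair The two canonical pericyte marker gene IDs
#'   (default `Cspg4`, `Pdgfrb`).
#' @slot nPlantedMarkersPerTissue Planted tissue-specific markers per tissue.
#' @slot nSharedMarkers Markers planted in more than one tissue; must not
#'   exceed the total planted budget `nTissues * nPlantedMarkersPerTissue`.
#' @slot nDecoysPerTissue Decoy markers per tissue, planted with detection
#'   probability `decoyPiIn`.
#' @slot piIn Probability a planted marker is detected (count > 0) in a
#'   pericyte of its target tissue.
#' @slot piOut Leak detection probability everywhere else.
#' @slot decoyPiIn In-pericyte detection probability of decoys (default 0.5).
#' @slot dualPosRate Probability a pericyte has count > 0 for both canonical
#'   markers.
#' @slot nbDispersion Negative-binomial size parameter shared across genes.
#' @slot libsizeLognormal `c(meanlog, sdlog)` of the per-cell library factor.
#' @slot seed Master seed.
#' @export
setClass("SimConfig", representation(
  nTissues = "integer",
  tissueNames = "character",
  nCells = "integer",
  nGenes = "integer",
  cellTypeProportions = "numeric",
  canonicalPair = "character",
  nPlantedMarkersPerTissue = "integer",
  nSharedMarkers = "integer",
  nDecoysPerTissue = "integer",
  piIn = "numeric",
  piOut = "numeric",
  decoyPiIn = "numeric",
  dualPosRate = "numeric",
  nbDispersion = "numeric",
  libsizeLognormal = "numeric",
  seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  req <- c("pericyte", "smooth_muscle", "fibroblast", "endothelial", "other")
  p <- object@cellTypeProportions
  if (!all(req %in% names(p)))
    msg <- c(msg, paste("cellTypeProportions must include:",
                        paste(setdiff(req, names(p)), collapse = ", ")))
  if (abs(sum(p) - 1) > 1e-9)
    msg <- c(msg, sprintf("cellTypeProportions sum to %g, not 1", sum(p)))
  if (any(p < 0)) msg <- c(msg, "cellTypeProportions must be non-negative")
  if (object@nTissues < 1L) msg <- c(msg, "nTissues must be positive")
  if (length(object@tissueNames) != object@nTissues)
    msg <- c(msg, "tissueNames length must equal nTissues")
  if (anyDuplicated(object@tissueNames))
    msg <- c(msg, "tissueNames must be unique")
  if (!length(object@nCells) %in% c(1L, object@nTissues))
    msg <- c(msg, "nCells must have length 1 or nTissues")
  if (any(object@nCells < 1L)) msg <- c(msg, "nCells must be positive")
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be positive")
  if (length(object@canonicalPair) != 2L ||
      object@canonicalPair[1] == object@canonicalPair[2])
    msg <- c(msg, "canonicalPair must be two distinct gene IDs")
  if (!(object@piIn > object@piOut))
    msg <- c(msg, "piIn must exceed piOut")
  for (nm in c("piIn", "piOut", "decoyPiIn", "dualPosRate")) {
    v <- slot(object, nm)
    if (v < 0 || v > 1) msg <- c(msg, sprintf("%s must lie in [0, 1]", nm))
  }
  if (object@nbDispersion <= 0) msg <- c(msg, "nbDispersion must be positive")
  if (length(object@libsizeLognormal) != 2L || object@libsizeLognormal[2] < 0)
    msg <- c(msg, "libsizeLognormal must be c(meanlog, sdlog >= 0)")
  if (object@nSharedMarkers >
      object@nTissues * object@nPlantedMarkersPerTissue)
    msg <- c(msg, "nSharedMarkers exceeds the planted-marker budget")
  if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' Defaults describe the study conditions the pipeline is validated under:
#' four tissues of 500 cells over a 1,200-gene universe, planted markers
#' detected in 95% of pericytes with 1% leak, decoys at 50%, and 90%
#' canonical dual-positivity.
#'
#' @param nTissues,tissueNames,nCells,nGenes,cellTypeProportions,canonicalPair
#'   See [SimConfig-class].
#' @param nPlantedMarkersPerTissue,nSharedMarkers,nDecoysPerTissue,piIn,piOut
#'   See [SimConfig-class].
#' @param decoyPiIn,dualPosRate,nbDispersion,libsizeLognormal,seed
#'   See [SimConfig-class].
#' @return A validated [SimConfig-class] object.
#' @export
#' @examples
#' cfg <- simConfig(nTissues = 2, nCells = 200, nGenes = 400, seed = 7)
#' cfg
simConfig <- function(nTissues = 4L,
                      tissueNames = NULL,
                      nCells = 500L,
                      nGenes = 1200L,
                      cellTypeProportions = c(pericyte = 0.12,
                                              smooth_muscle = 0.15,
                                              fibroblast = 0.25,
                                              endothelial = 0.25,
                                              other = 0.23),
                      canonicalPair = c("Cspg4", "Pdgfrb"),
                      nPlantedMarkersPerTissue = 10L,
                      nSharedMarkers = 4L,
                      nDecoysPerTissue = 4L,
                      piIn = 0.95,
                      piOut = 0.01,
                      decoyPiIn = 0.5,
                      dualPosRate = 0.9,
                      nbDispersion = 2,
                      libsizeLognormal = c(0, 0.25),
                      seed = 1L) {
  if (is.null(tissueNames)) {
    base <- c("lung", "heart", "kidney", "bladder")
    tissueNames <- if (nTissues <= 4L) base[seq_len(nTissues)]
      else c(base, paste0("tissue", seq(5L, nTissues)))
  }
  new("SimConfig",
      nTissues = as.integer(nTissues),
      tissueNames = tissueNames,
      nCells = as.integer(nCells),
      nGenes = as.integer(nGenes),
      cellTypeProportions = cellTypeProportions,
      canonicalPair = canonicalPair,
      nPlantedMarkersPerTissue = as.integer(nPlantedMarkersPerTissue),
      nSharedMarkers = as.integer(nSharedMarkers),
      nDecoysPerTissue = as.integer(nDecoysPerTissue),
      piIn = piIn, piOut = piOut, decoyPiIn = decoyPiIn,
      dualPosRate = dualPosRate, nbDispersion = nbDispersion,
      libsizeLognormal = libsizeLognormal, seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nTissues, "tissue(s) [",
      paste(object@tissueNames, collapse = ", "), "]\n")
  cat("  cells/tissue:", paste(object@nCells, collapse = ","),
      " genes:", object@nGenes, "\n")
  cat("  planted/tissue:", object@nPlantedMarkersPerTissue,
      " shared:", object@nSharedMarkers,
      " decoys/tissue:", object@nDecoysPerTissue, "\n")
  cat(sprintf("  piIn=%.3g piOut=%.3g dualPosRate=%.3g seed=%d\n",
              object@piIn, object@piOut, object@dualPosRate, object@seed))
})

# ---------------------------------------------------------------------------
# GateParams / GateResult
# ---------------------------------------------------------------------------

#' Parameters of the stringent-pericyte gate
#'
#' @slot markerA,markerB The two canonical marker gene IDs (distinct).
#' @slot minDualFraction Minimum fraction of dual-positive cells a cluster
#'   must reach to count as pericyte-enriched (default 0.05, below the lowest
#'   stringent proportion reported in real tissue so a comparable cluster
#'   qualifies).
#' @slot foldOverGlobal Required fold of the cluster's dual-positive fraction
#'   over the tissue-wide dual-positive fraction (default 5).
#' @export
setClass("GateParams", representation(
  markerA = "character", markerB = "character",
  minDualFraction = "numeric", foldOverGlobal = "numeric"))

setValidity("GateParams", function(object) {
  msg <- character()
  if (length(object@markerA) != 1L || length(object@markerB) != 1L ||
      object@markerA == object@markerB)
    msg <- c(msg, "markerA and markerB must be distinct single gene IDs")
  if (object@minDualFraction <= 0 || object@foldOverGlobal <= 0)
    msg <- c(msg, "thresholds must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname GateParams-class
#' @param markerA,markerB,minDualFraction,foldOverGlobal See slots.
#' @return A [GateParams-class] object.
#' @export
#' @examples
#' gateParams()
gateParams <- function(markerA = "Cspg4", markerB = "Pdgfrb",
                       minDualFraction = 0.05, foldOverGlobal = 5) {
  new("GateParams", markerA = markerA, markerB = markerB,
      minDualFraction = minDualFraction, foldOverGlobal = foldOverGlobal)
}

#' Result of gating stringent pericytes in one tissue
#'
#' @slot tissue Tissue label.
#' @slot enrichedClusters Integer IDs of pericyte-enriched clusters.
#' @slot stringentMask Per-cell logical: inside an enriched cluster and
#'   count > 0 for both canonical markers.
#' @slot summary One-row data.frame: tissue, n_stringent, n_enriched_cells,
#'   proportion.
#' @export
setClass("GateResult", representation(
  tissue = "character", enrichedClusters = "integer",
  stringentMask = "logical", summary = "data.frame"))

setValidity("GateResult", function(object) {
  s <- object@summary
  msg <- character()
  if (nrow(s) != 1L ||
      !all(c("tissue", "n_stringent", "n_enriched_cells", "proportion")
           %in% names(s)))
    msg <- c(msg, "summary must be a one-row gate summary table")
  else {
    if (s$n_stringent != sum(object@stringentMask))
      msg <- c(msg, "summary n_stringent inconsistent with mask")
    if (s$n_enriched_cells > 0 &&
        abs(s$proportion - s$n_stringent / s$n_enriched_cells) > 1e-12)
      msg <- c(msg, "proportion must equal n_stringent / n_enriched_cells")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn GateResult-class IDs of the pericyte-enriched clusters.
#' @param x A `GateResult`.
#' @export
enrichedClusters <- function(x) {
  stopifnot(is(x, "GateResult"))
  x@enrichedClusters
}

#' @describeIn GateResult-class Per-cell stringent-pericyte mask.
#' @export
stringentMask <- function(x) {
  stopifnot(is(x, "GateResult"))
  x@stringentMask
}

#' @describeIn GateResult-class One-row per-tissue summary table.
#' @export
gateSummaryTable <- function(x) {
  stopifnot(is(x, "GateResult"))
  x@summary
}

setMethod("show", "GateResult", function(object) {
  s <- object@summary
  cat(sprintf(
    "GateResult [%s]: clusters {%s}; %d stringent of %d enriched-cluster cells (%.1f%%)\n",
    object@tissue, paste(object@enrichedClusters, collapse = ","),
    s$n_stringent, s$n_enriched_cells, 100 * s$proportion))
})

# ---------------------------------------------------------------------------
# PcaEmbedding
# ---------------------------------------------------------------------------

#' PCA embedding of cells
#'
#' @slot scores cells x nPcs score matrix.
#' @slot varExplained Per-component explained-variance fraction,
#'   non-increasing.
#' @slot rotation genes x nPcs loadings over the variable genes used.
#' @slot geneIds The variable genes the embedding was fit on.
#' @export
setClass("PcaEmbedding", representation(
  scores = "matrix", varExplained = "numeric",
  rotation = "matrix", geneIds = "character"))

setValidity("PcaEmbedding", function(object) {
  msg <- character()
  if (ncol(object@scores) != length(object@varExplained))
    msg <- c(msg, "one varExplained entry per component required")
  if (is.unsorted(rev(object@varExplained), strictly = FALSE) &&
      any(diff(object@varExplained) > 1e-8))
    msg <- c(msg, "varExplained must be non-increasing")
  if (length(msg)) msg else TRUE
})

#' @describeIn PcaEmbedding-class Cell score matrix.
#' @param x A `PcaEmbedding`.
#' @export
pcaScores <- function(x) {
  stopifnot(is(x, "PcaEmbedding"))
  x@scores
}

#' @describeIn PcaEmbedding-class Explained-variance fractions.
#' @export
varExplained <- function(x) {
  stopifnot(is(x, "PcaEmbedding"))
  x@varExplained
}

setMethod("show", "PcaEmbedding", function(object) {
  cat(sprintf("PcaEmbedding: %d cells x %d PCs (%.1f%% variance)\n",
              nrow(object@scores), ncol(object@scores),
              100 * sum(object@varExplained)))
})

# ---------------------------------------------------------------------------
# SnnGraph
# ---------------------------------------------------------------------------

#' Shared-nearest-neighbor graph
#'
#' Undirected cell graph weighted by Jaccard similarity of k-nearest-neighbor
#' sets; weights in (0, 1], no self-loops, symmetric adjacency.
#'
#' @slot adjacency Symmetric sparse `dgCMatrix` of edge weights.
#' @export
setClass("SnnGraph", representation(adjacency = "dgCMatrix"))

setValidity("SnnGraph", function(object) {
  a <- object@adjacency
  msg <- character()
  if (nrow(a) != ncol(a)) msg <- c(msg, "adjacency must be square")
  if (any(Matrix::diag(a) != 0)) msg <- c(msg, "self-loops are not allowed")
  if (length(a@x) && (any(a@x <= 0) || any(a@x > 1)))
    msg <- c(msg, "weights must lie in (0, 1]")
  if (!Matrix::isSymmetric(a, tol = 0))
    msg <- c(msg, "adjacency must be symmetric")
  if (length(msg)) msg else TRUE
})

#' @describeIn SnnGraph-class Sparse symmetric adjacency matrix.
#' @param x An `SnnGraph`.
#' @export
snnAdjacency <- function(x) {
  stopifnot(is(x, "SnnGraph"))
  x@adjacency
}

setMethod("show", "SnnGraph", function(object) {
  a <- object@adjacency
  cat(sprintf("SnnGraph: %d cells, %d edges\n", nrow(a), length(a@x) / 2))
})

# ---------------------------------------------------------------------------
# VennColocalization
# ---------------------------------------------------------------------------

#' Three-set spatial co-localization partition
#'
#' Sizes of the seven regions of the partition generated by two per-gene spot
#' sets (A, B) and the cluster-designated pericyte spot set (P), plus overlap
#' percentages under an explicit convention: `pct_overlap_A = 100 |A ∩ P|/|P|`,
#' `pct_overlap_B = 100 |B ∩ P|/|P|`, `pct_both_in_P = 100 |A ∩ B ∩ P|/|P|`.
#'
#' @slot regionSizes Named numeric(7): `A_only`, `B_only`, `P_only`, `AB_only`,
#'   `AP_only`, `BP_only`, `ABP`.
#' @slot percentages Named numeric(3): `pct_overlap_A`, `pct_overlap_B`,
#'   `pct_both_in_P` (NA when P is empty).
#' @slot setSizes Named numeric(3): |A|, |B|, |P|.
#' @export
setClass("VennColocalization", representation(
  regionSizes = "numeric", percentages = "numeric", setSizes = "numeric"))

setValidity("VennColocalization", function(object) {
  r <- object@regionSizes
  nm <- c("A_only", "B_only", "P_only", "AB_only", "AP_only", "BP_only", "ABP")
  msg <- character()
  if (!identical(names(r), nm)) msg <- c(msg, "regionSizes misnamed")
  if (any(r < 0)) msg <- c(msg, "region sizes must be non-negative")
  s <- object@setSizes
  if (!is.na(s["A"]) &&
      s[["A"]] != r[["A_only"]] + r[["AB_only"]] + r[["AP_only"]] + r[["ABP"]])
    msg <- c(msg, "|A| must equal the sum of its regions")
  if (length(msg)) msg else TRUE
})

#' @describeIn VennColocalization-class Named region sizes.
#' @param x A `VennColocalization`.
#' @export
vennRegionSizes <- function(x) {
  stopifnot(is(x, "VennColocalization"))
  x@regionSizes
}

#' @describeIn VennColocalization-class Overlap percentages (denominator |P|).
#' @export
vennPercentages <- function(x) {
  stopifnot(is(x, "VennColocalization"))
  x@percentages
}

setMethod("show", "VennColocalization", function(object) {
  cat("VennColocalization (|A|,|B|,|P| =",
      paste(object@setSizes, collapse = ","), ")\n")
  print(object@regionSizes)
  print(round(object@percentages, 2))
})
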