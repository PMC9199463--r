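#' Find pericyte-enriched clusters
#'
#' A cluster is pericyte-enriched when the fraction of its cells with raw
#' count > 0 for both canonical markers reaches both an absolute floor
#' (`minDualFraction`) and a fold over the tissue-wide dual-positive fraction
#' (`foldOverGlobal`). "Expressing" means raw count > 0 throughout; no
#' magnitude threshold is applied. Several clusters may qualify; they are
#' pooled downstream.
#'
#' @param counts `SingleCellExperiment` with a `counts` assay, or a sparse
#'   genes x cells count matrix.
#' @param labels Integer cluster labels (0-based), one per cell.
#' @param params A [GateParams-class].
#' @return Sorted integer vector of enriched cluster IDs (possibly empty,
#'   with a warning).
#' @export
findEnrichedClusters <- function(counts, labels, params = gateParams()) {
  if (is(counts, "SummarizedExperiment")) counts <- assay(counts, "counts")
  if (ncol(counts) != length(labels))
    stopf("labels must cover all %d cells", ncol(counts))
  dual <- dualPositive(counts, params)
  globalFrac <- mean(dual)
  ids <- sort(unique(labels))
  frac <- vapply(ids, function(c) mean(dual[labels == c]), 0)
  enriched <- ids[frac >= params@minDualFraction &
                  frac >= params@foldOverGlobal * globalFrac]
  if (!length(enriched))
    warnf("no cluster meets the dual-positive enrichment rule (max fraction %.3g)",
          max(frac))
  as.integer(enriched)
}

dualPositive <- function(counts, params) {
  for (g in c(params@markerA, params@markerB))
    if (!g %in% rownames(counts))
      stopf("canonical marker '%s' absent from the gene universe", g)
  a <- counts[params@markerA, ]
  b <- counts[params@markerB, ]
  as.vector(a > 0 & b > 0)
}

#' Gate stringent pericytes
#'
#' A cell is a stringent pericyte when its cluster is pericyte-enriched and
#' it has raw count > 0 for both canonical markers.
#'
#' @inheritParams findEnrichedClusters
#' @param enriched Integer vector of enriched cluster IDs (non-empty).
#' @return Logical per-cell mask.
#' @export
gateStringent <- function(counts, labels, enriched, params = gateParams()) {
  if (is(counts, "SummarizedExperiment")) counts <- assay(counts, "counts")
  if (!length(enriched)) stopf("enriched cluster set must be non-empty")
  dualPositive(counts, params) & labels %in% enriched
}

#' Summarize a gate for one tissue
#'
#' @param mask Logical stringent-pericyte mask.
#' @param labels Integer cluster labels.
#' @param enriched Enriched cluster IDs.
#' @param tissue Tissue label.
#' @return One-row data.frame: `tissue, n_stringent, n_enriched_cells,
#'   proportion` (0 when no enriched-cluster cells exist).
#' @export
gateSummary <- function(mask, labels, enriched, tissue) {
  stopifnot(length(mask) == length(labels))
  nEnr <- sum(labels %in% enriched)
  nStr <- sum(mask)
  data.frame(tissue = tissue, n_stringent = nStr, n_enriched_cells = nEnr,
             proportion = if (nEnr > 0) nStr / nEnr else 0)
}

#' Run the full stringent-pericyte gate for one tissue
#'
#' Convenience wrapper: [findEnrichedClusters()], [gateStringent()],
#' [gateSummary()] bundled into a validated [GateResult-class]. When no
#' cluster qualifies, the returned result has an empty cluster set and an
#' all-FALSE mask (the pipeline skips downstream stages for that tissue).
#'
#' @inheritParams findEnrichedClusters
#' @param tissue Tissue label (default: taken from `colData(counts)$tissue`).
#' @return A [GateResult-class].
#' @export
gateCells <- function(counts, labels, params = gateParams(), tissue = NULL) {
  if (is.null(tissue))
    tissue <- if (is(counts, "SummarizedExperiment") &&
                  "tissue" %in% names(colData(counts)))
      as.character(colData(counts)$tissue[1]) else "tissue"
  enriched <- findEnrichedClusters(counts, labels, params)
  mask <- if (length(enriched))
    gateStringent(counts, labels, enriched, params)
  else rep(FALSE, length(labels))
  new("GateResult", tissue = tissue, enrichedClusters = enriched,
      stringentMask = mask,
      summary = gateSummary(mask, labels, enriched, tissue))
}
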