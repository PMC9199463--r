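#' Two-sided Wilcoxon rank-sum test
#'
#' The statistic is the rank sum `W` of group `x` (mean `n(n+m+1)/2` under
#' the null). `exact` mode enumerates all `choose(n+m, n)` assignments of the
#' observed (tied) ranks to the two groups and reports the fraction with
#' `|W - mean|` at least the observed deviation. `normal` mode uses the
#' tie-corrected normal approximation with a continuity correction of 0.5.
#' When every value is tied the p-value is 1 by convention. `auto` picks
#' exact when `n + m <= 12`.
#'
#' @param x,y Numeric value vectors (each non-empty).
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return List with `statistic` (rank sum of `x`) and `p` (two-sided).
#' @export
#' @examples
#' wilcoxonTest(c(1, 2, 3), c(4, 5, 6), mode = "exact")$p   # 0.1
wilcoxonTest <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  n <- length(x)
  m <- length(y)
  if (n < 1L || m < 1L) stopf("both groups must be non-empty")
  N <- n + m
  if (mode == "auto") mode <- if (N <= 12L) "exact" else "normal"
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n)])
  mu <- n * (N + 1) / 2
  if (mode == "exact") {
    dev <- abs(W - mu)
    combs <- utils::combn(N, n)
    sums <- colSums(matrix(r[combs], nrow = n))
    p <- mean(abs(sums - mu) >= dev - 1e-12)
  } else {
    ties <- table(r)
    tieSum <- sum(ties^3 - ties)
    sigma2 <- n * m / 12 * ((N + 1) - tieSum / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      d <- W - mu
      z <- (d - sign(d) * min(0.5, abs(d))) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  list(statistic = W, p = p)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_{j >= i} p_(j) * m / j`, clipped at 1, returned in the input
#' order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same length and order.
#' @export
#' @examples
#' bhAdjust(c(0.005, 0.1))   # 0.01, 0.1
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stopf("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0L) return(numeric(0))
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

#' Maximum expressing fraction over non-enriched clusters (pct3)
#'
#' For each gene, the fraction of cells with raw count > 0 is computed within
#' every cluster outside the pericyte-enriched set; pct3 is the maximum of
#' those fractions.
#'
#' @param counts `SingleCellExperiment` with a `counts` assay or sparse
#'   genes x cells count matrix.
#' @param labels Integer cluster labels per cell.
#' @param enriched Enriched cluster IDs to exclude.
#' @return Named numeric vector, one pct3 per gene.
#' @export
pct3PerGene <- function(counts, labels, enriched) {
  if (is(counts, "SummarizedExperiment")) counts <- assay(counts, "counts")
  ids <- setdiff(sort(unique(labels)), enriched)
  if (!length(ids)) stopf("all clusters are enriched; pct3 is undefined")
  out <- rep(0, nrow(counts))
  for (c in ids) {
    cells <- labels == c
    frac <- Matrix::rowSums(counts[, cells, drop = FALSE] > 0) / sum(cells)
    out <- pmax(out, frac)
  }
  names(out) <- rownames(counts)
  out
}

#' Differential expression of stringent pericytes vs all other cells
#'
#' For every gene detected (count > 0) in at least `minCells` cells, a
#' two-sided Wilcoxon rank-sum test (normal approximation with tie correction
#' and continuity correction) compares the log-normalized values of stringent
#' pericytes against all other cells of the tissue (including non-stringent
#' cells inside enriched clusters). P-values are Benjamini-Hochberg adjusted
#' across tested genes. The fold change is
#' `avg_log2fc = log2((mean(expm1(x_stringent)) + 1) /
#' (mean(expm1(x_other)) + 1))`. Expression fractions come from raw counts:
#' pct1 within stringent cells, pct2 within all other cells, pct3 via
#' [pct3PerGene()]. Selection flags are set by [selectMarkers()] with its
#' default thresholds.
#'
#' @param sce `SingleCellExperiment` carrying `counts` and `logcounts`.
#' @param mask Logical stringent-pericyte mask (>= 3 TRUE and >= 3 FALSE).
#' @param labels Integer cluster labels.
#' @param enriched Enriched cluster IDs.
#' @param minCells Minimum detecting cells for a gene to be tested
#'   (default 3).
#' @return A [S4Vectors::DataFrame] with columns `gene, avg_log2fc, p, p_adj,
#'   pct1, pct2, pct3, selected, high_specificity`, one row per tested gene.
#' @export
computeMarkerTable <- function(sce, mask, labels, enriched, minCells = 3L) {
  counts <- assay(sce, "counts")
  if (!"logcounts" %in% SummarizedExperiment::assayNames(sce))
    stopf("run logNormalize() first: no 'logcounts' assay")
  norm <- assay(sce, "logcounts")
  if (sum(mask) < 3L || sum(!mask) < 3L)
    stopf("need at least 3 stringent and 3 other cells (have %d / %d)",
          sum(mask), sum(!mask))
  detected <- Matrix::rowSums(counts > 0)
  tested <- which(detected >= minCells)
  if (!length(tested)) stopf("no gene is detected in at least %d cells", minCells)
  nStr <- sum(mask)
  nOth <- sum(!mask)
  genes <- rownames(sce)[tested]
  pct1 <- Matrix::rowSums(counts[tested, mask, drop = FALSE] > 0) / nStr
  pct2 <- Matrix::rowSums(counts[tested, !mask, drop = FALSE] > 0) / nOth
  pct3 <- pct3PerGene(counts, labels, enriched)[tested]
  p <- numeric(length(tested))
  fc <- numeric(length(tested))
  normT <- as(norm, "CsparseMatrix")
  chunk <- 400L
  for (start in seq(1L, length(tested), by = chunk)) {
    idx <- tested[start:min(start + chunk - 1L, length(tested))]
    block <- as.matrix(normT[idx, , drop = FALSE])
    for (r in seq_len(nrow(block))) {
      v <- block[r, ]
      res <- wilcoxonTest(v[mask], v[!mask], mode = "normal")
      o <- start + r - 1L
      p[o] <- res$p
      fc[o] <- log2((mean(expm1(v[mask])) + 1) / (mean(expm1(v[!mask])) + 1))
    }
  }
  tab <- S4Vectors::DataFrame(
    gene = genes, avg_log2fc = fc, p = p, p_adj = bhAdjust(p),
    pct1 = pct1, pct2 = pct2, pct3 = pct3,
    selected = FALSE, high_specificity = FALSE)
  rownames(tab) <- genes
  selectMarkers(tab)
}

#' Apply marker selection thresholds
#'
#' `selected` is TRUE when `p_adj < alpha`, `pct1 > pct1Min` and
#' `pct2 < pct2Max`; `high_specificity` additionally requires
#' `pct3 < pct3Max`. All inequalities are strict.
#'
#' @param table Marker table ([computeMarkerTable()] output or data.frame
#'   with the same statistic columns).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param pct1Min Minimum stringent-cell expressing fraction (default 0.80).
#' @param pct2Max Maximum other-cell expressing fraction (default 0.05).
#' @param pct3Max Maximum non-enriched-cluster expressing fraction for the
#'   high-specificity flag (default 0.10).
#' @return The table with `selected` and `high_specificity` set.
#' @export
selectMarkers <- function(table, alpha = 0.05, pct1Min = 0.80,
                          pct2Max = 0.05, pct3Max = 0.10) {
  table$selected <- table$p_adj < alpha & table$pct1 > pct1Min &
    table$pct2 < pct2Max
  table$high_specificity <- table$selected & table$pct3 < pct3Max
  table
}

#' Cross-tissue Venn partition of marker sets
#'
#' Every gene in the union of the per-tissue marker sets is assigned to
#' exactly one membership pattern: the set of tissues whose marker sets
#' contain it. Pattern labels join tissue names with `"+"` in the input
#' tissue order.
#'
#' @param markerSets Named list (tissue -> character vector of gene IDs),
#'   length >= 2.
#' @return Data.frame with columns `pattern`, `n`, `genes` (comma-joined,
#'   sorted), one row per non-empty pattern.
#' @export
crossTissueVenn <- function(markerSets) {
  if (length(markerSets) < 2L) stopf("need marker sets for at least 2 tissues")
  tissues <- names(markerSets)
  if (is.null(tissues) || any(!nzchar(tissues)))
    stopf("markerSets must be a named list")
  universe <- sort(unique(unlist(markerSets)))
  if (!length(universe))
    return(data.frame(pattern = character(0), n = integer(0),
                      genes = character(0)))
  pattern <- vapply(universe, function(g) {
    paste(tissues[vapply(markerSets, function(s) g %in% s, TRUE)],
          collapse = "+")
  }, "")
  split <- split(universe, pattern)
  data.frame(pattern = names(split),
             n = lengths(split),
             genes = vapply(split, function(g) paste(sort(g), collapse = ","), ""),
             row.names = NULL)
}
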