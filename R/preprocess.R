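#' Log-normalize a count matrix
#'
#' Library-size normalization followed by a natural-log transform with
#' pseudocount 1: `x_gj = ln(1 + c_gj * S / L_j)` where `L_j` is the library
#' size (column sum) of cell j and `S` the scale factor (default 10,000, the
#' droplet convention). Zero counts map to zero, so sparsity is preserved.
#'
#' @param counts A `SingleCellExperiment` with a `counts` assay, or a sparse
#'   genes x cells count matrix.
#' @param scaleFactor Positive scale factor S.
#' @return The input object with a `logcounts` assay added (and
#'   `metadata()$scaleFactor` recorded), or the normalized sparse matrix when
#'   a bare matrix was given.
#' @export
#' @examples
#' m <- Matrix::sparseMatrix(i = 1, j = 1, x = 1, dims = c(2, 2),
#'                           dimnames = list(c("g1", "g2"), c("c1", "c2")))
#' m[2, 2] <- 100
#' logNormalize(m)[1, 1]   # ln(1 + 1*1e4/1)
logNormalize <- function(counts, scaleFactor = 1e4) {
  stopifnot(is.numeric(scaleFactor), scaleFactor > 0)
  sce <- NULL
  if (is(counts, "SummarizedExperiment")) {
    sce <- counts
    counts <- assay(sce, "counts")
  }
  counts <- as(as(counts, "CsparseMatrix"), "dMatrix")
  L <- Matrix::colSums(counts)
  if (any(L == 0)) {
    bad <- colnames(counts)[L == 0] %||% which(L == 0)
    stopf("cells with zero library size: %s",
          paste(utils::head(bad, 10), collapse = ", "))
  }
  norm <- counts %*% Matrix::Diagonal(x = scaleFactor / L)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(counts)
  norm <- as(norm, "CsparseMatrix")
  if (is.null(sce)) return(norm)
  SummarizedExperiment::assay(sce, "logcounts") <- norm
  metadata(sce)$scaleFactor <- scaleFactor
  sce
}

#' Select highly variable genes by the VST method
#'
#' Per gene, the mean and variance of the raw counts are computed; a local
#' polynomial regression (loess, span 0.3, degree 2) of `log10(variance)` on
#' `log10(mean)` over genes with positive variance supplies an expected
#' standard deviation; counts are standardized with the expected sd, clipped
#' at `sqrt(n_cells)` in absolute value, and the gene's variability score is
#' the sample variance of the clipped standardized values. Constant genes
#' score 0. Returns the `nTop` genes by decreasing score, ties broken by
#' gene ID.
#'
#' @param counts A `SingleCellExperiment` with a `counts` assay, or a
#'   genes x cells count matrix.
#' @param nTop Number of genes to return (default 2,000). If larger than the
#'   gene universe, all genes are returned with a warning.
#' @return Character vector of gene IDs, most variable first, with the score
#'   vector attached as attribute `"score"`.
#' @export
selectHvgVst <- function(counts, nTop = 2000) {
  if (is(counts, "SummarizedExperiment")) counts <- assay(counts, "counts")
  counts <- as(as(counts, "CsparseMatrix"), "dMatrix")
  nGenes <- nrow(counts)
  nCells <- ncol(counts)
  if (nCells < 2L) stopf("VST selection needs at least 2 cells")
  genes <- rownames(counts) %||% as.character(seq_len(nGenes))
  mu <- Matrix::rowMeans(counts)
  ex2 <- Matrix::rowMeans(counts^2)
  v <- (ex2 - mu^2) * nCells / (nCells - 1)
  v <- pmax(v, 0)
  score <- numeric(nGenes)
  pos <- v > 0
  if (sum(pos) >= 4L) {
    fit <- stats::loess(log10(v[pos]) ~ log10(mu[pos]), span = 0.3, degree = 2)
    sdExp <- sqrt(10^as.numeric(stats::predict(fit)))
    clip <- sqrt(nCells)
    # Sparse-aware clipped standardized variance: zeros contribute the
    # (clipped) standardized value of zero, nonzeros are handled explicitly.
    cT <- as(counts[pos, , drop = FALSE], "TsparseMatrix")
    rowIdx <- cT@i + 1L
    xs <- cT@x
    muP <- mu[pos]
    z0 <- pmin(pmax((0 - muP) / sdExp, -clip), clip)
    zNz <- pmin(pmax((xs - muP[rowIdx]) / sdExp[rowIdx], -clip), clip)
    nnz <- tabulate(rowIdx, nbins = sum(pos))
    sumZ <- z0 * (nCells - nnz) +
      as.numeric(rowsumFast(zNz, rowIdx, sum(pos)))
    sumZ2 <- z0^2 * (nCells - nnz) +
      as.numeric(rowsumFast(zNz^2, rowIdx, sum(pos)))
    zBar <- sumZ / nCells
    score[pos] <- (sumZ2 - nCells * zBar^2) / (nCells - 1)
    score[pos][sdExp == 0 | !is.finite(score[pos])] <- 0
  }
  if (nTop > nGenes) {
    warnf("nTop (%d) exceeds the number of genes (%d); returning all genes",
          nTop, nGenes)
    nTop <- nGenes
  }
  ord <- order(-score, genes)
  top <- genes[ord][seq_len(nTop)]
  names(score) <- genes
  attr(top, "score") <- score
  top
}

rowsumFast <- function(x, group, nbins) {
  out <- numeric(nbins)
  agg <- rowsum(x, group)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Scale variable genes and compute a PCA embedding
#'
#' Per-gene z-scoring of the log-normalized values over cells, clipped to
#' `[-clip, clip]` (default 10), then PCA of the resulting matrix by singular
#' value decomposition. The sign of each component is fixed so that its
#' largest-magnitude gene loading is positive (ties to the lower gene index),
#' making the embedding deterministic across linear-algebra backends.
#' Explained-variance fractions are singular values squared over the total
#' variance of the scaled matrix.
#'
#' @param norm A `SingleCellExperiment` with a `logcounts` assay, or a
#'   genes x cells matrix of normalized values.
#' @param hvgs Character vector of variable genes to use (must exist).
#' @param nPcs Number of components; must be < min(|hvgs|, nCells).
#' @param clip Absolute z-score clip (default 10).
#' @return A [PcaEmbedding-class] with cell scores, explained-variance
#'   fractions, gene loadings and the gene list used.
#' @export
scaleAndPca <- function(norm, hvgs, nPcs, clip = 10) {
  if (is(norm, "SummarizedExperiment")) norm <- assay(norm, "logcounts")
  if (is.null(rownames(norm))) stopf("normalized matrix must have gene names")
  missing <- setdiff(hvgs, rownames(norm))
  if (length(missing))
    stopf("variable genes absent from the matrix: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  x <- as.matrix(norm[hvgs, , drop = FALSE])
  nCells <- ncol(x)
  if (nPcs >= min(length(hvgs), nCells))
    stopf("nPcs (%d) must be smaller than min(n variable genes, n cells) = %d",
          nPcs, min(length(hvgs), nCells))
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  sdv[sdv == 0] <- Inf          # constant genes scale to all-zero rows
  z <- (x - mu) / sdv
  z[z > clip] <- clip
  z[z < -clip] <- -clip
  y <- t(z)                     # cells x genes
  # SVD via the smaller Gram matrix.
  totalVar <- sum(y^2) / (nCells - 1)
  if (nrow(y) <= ncol(y)) {
    g <- tcrossprod(y)
    eig <- eigen(g, symmetric = TRUE)
    d2 <- pmax(eig$values[seq_len(nPcs)], 0)
    u <- eig$vectors[, seq_len(nPcs), drop = FALSE]
    d <- sqrt(d2)
    vOk <- d > 1e-12
    v <- matrix(0, ncol(y), nPcs)
    v[, vOk] <- crossprod(y, u[, vOk, drop = FALSE]) /
      rep(d[vOk], each = ncol(y))
  } else {
    g <- crossprod(y)
    eig <- eigen(g, symmetric = TRUE)
    d2 <- pmax(eig$values[seq_len(nPcs)], 0)
    v <- eig$vectors[, seq_len(nPcs), drop = FALSE]
    d <- sqrt(d2)
    uOk <- d > 1e-12
    u <- matrix(0, nrow(y), nPcs)
    u[, uOk] <- (y %*% v[, uOk, drop = FALSE]) / rep(d[uOk], each = nrow(y))
  }
  # Sign convention: largest-|loading| gene positive per component.
  for (k in seq_len(nPcs)) {
    j <- which.max(abs(v[, k]))
    if (length(j) && v[j, k] < 0) {
      v[, k] <- -v[, k]
      u[, k] <- -u[, k]
    }
  }
  scores <- u * rep(d, each = nrow(u))
  rownames(scores) <- colnames(x)
  colnames(scores) <- paste0("PC", seq_len(nPcs))
  rownames(v) <- hvgs
  colnames(v) <- colnames(scores)
  ve <- if (totalVar > 0) (d2 / (nCells - 1)) / totalVar else rep(0, nPcs)
  new("PcaEmbedding", scores = scores, varExplained = ve,
      rotation = v, geneIds = hvgs)
}
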