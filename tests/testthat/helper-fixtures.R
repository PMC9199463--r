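suppressPackageStartupMessages({
  library(Matrix)
  library(SingleCellExperiment)
})

# Small simulation configuration for fast unit tests.
tinySimConfig <- function(seed = 11L, nTissues = 2L, nCells = 250L,
                          nGenes = 400L, ...) {
  simConfig(nTissues = nTissues, nCells = nCells, nGenes = nGenes,
            seed = seed, ...)
}

# Random sparse count matrix with dimnames.
randomCounts <- function(nGenes, nCells, seed = 1L, density = 0.3) {
  set.seed(seed)
  m <- matrix(0L, nGenes, nCells)
  nnz <- round(density * nGenes * nCells)
  idx <- sample(nGenes * nCells, nnz)
  m[idx] <- rpois(nnz, 3) + 1L
  dimnames(m) <- list(sprintf("gene%03d", seq_len(nGenes)),
                      sprintf("cell%03d", seq_len(nCells)))
  as(m, "CsparseMatrix")
}

countsToSce <- function(m, tissue = "test") {
  SingleCellExperiment(
    assays = list(counts = m),
    colData = S4Vectors::DataFrame(tissue = rep(tissue, ncol(m)),
                                   row.names = colnames(m)))
}

# All set partitions of 1..n as lists of integer label vectors
# (restricted-growth strings); independent oracle helper for Louvain.
allPartitions <- function(n) {
  out <- list()
  rec <- function(labels, nextMax) {
    k <- length(labels)
    if (k == n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (v in seq_len(nextMax + 1L)) {
      rec(c(labels, v), max(nextMax, v))
    }
  }
  rec(integer(0), 0L)
  out
}

# Brute-force maximum modularity over all partitions (n <= 8).
bruteForceMaxModularity <- function(adj, resolution) {
  parts <- allPartitions(nrow(adj))
  best <- -Inf
  for (p in parts) {
    q <- graphModularity(adj, p, resolution)
    if (q > best) best <- q
  }
  best
}

# Exact two-sided Wilcoxon p by full enumeration, written independently of
# the package implementation (works on values, not precomputed ranks).
bruteWilcoxP <- function(x, y) {
  n <- length(x)
  N <- n + length(y)
  vals <- c(x, y)
  r <- rank(vals)
  obs <- abs(sum(r[seq_len(n)]) - n * (N + 1) / 2)
  hits <- 0L
  total <- 0L
  for (comb in asplit(combn(N, n), 2)) {
    total <- total + 1L
    if (abs(sum(r[comb]) - n * (N + 1) / 2) >= obs - 1e-12) hits <- hits + 1L
  }
  hits / total
}
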