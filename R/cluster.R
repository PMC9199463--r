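#' k-nearest-neighbor sets in PC space
#'
#' Exact Euclidean nearest neighbors. Each cell's neighbor set contains the
#' cell itself plus its `k - 1` nearest others; distance ties are broken by
#' the lower cell index, so the result is deterministic.
#'
#' @param embedding A [PcaEmbedding-class] or a cells x d coordinate matrix.
#' @param k Neighborhood size including self (default 20); must be < nCells.
#' @return Integer matrix, one row per cell, `k` columns of neighbor indices
#'   (self first, then by increasing distance).
#' @export
knnNeighbors <- function(embedding, k = 20) {
  x <- if (is(embedding, "PcaEmbedding")) pcaScores(embedding) else
    as.matrix(embedding)
  n <- nrow(x)
  if (k >= n) stopf("k (%d) must be smaller than the number of cells (%d)", k, n)
  if (k < 1) stopf("k must be at least 1")
  d2 <- as.matrix(stats::dist(x))^2
  out <- matrix(0L, n, k)
  idx <- seq_len(n)
  for (i in seq_len(n)) {
    di <- d2[, i]
    di[i] <- -Inf                       # self always first
    ord <- order(di, idx)
    out[i, ] <- ord[seq_len(k)]
  }
  out
}

#' Shared-nearest-neighbor graph with Jaccard weights
#'
#' Edge weight between cells i and j is the Jaccard similarity of their
#' k-nearest-neighbor sets, `|N_i ∩ N_j| / |N_i ∪ N_j|`; edges with weight
#' below `prune` are removed, as are self-loops.
#'
#' @param neighbors Integer neighbor matrix from [knnNeighbors()].
#' @param prune Minimum retained weight (default 1/15).
#' @return An [SnnGraph-class].
#' @export
snnJaccard <- function(neighbors, prune = 1 / 15) {
  n <- nrow(neighbors)
  k <- ncol(neighbors)
  inc <- Matrix::sparseMatrix(
    i = rep(seq_len(n), k), j = as.vector(neighbors), x = 1, dims = c(n, n))
  inter <- Matrix::tcrossprod(inc)       # |N_i ∩ N_j|
  inter <- as(inter, "CsparseMatrix")
  Matrix::diag(inter) <- 0
  inter <- Matrix::drop0(inter)
  if (length(inter@x)) {
    w <- inter@x / (2 * k - inter@x)     # all sets have size k
    inter@x <- ifelse(w < prune, 0, w)
    inter <- Matrix::drop0(inter)
  }
  adj <- as(as(as(inter, "generalMatrix"), "CsparseMatrix"), "dMatrix")
  new("SnnGraph", adjacency = adj)
}

#' Modularity of a partition
#'
#' `Q(gamma) = (1/2m) * sum_ij [A_ij - gamma * k_i k_j / (2m)] *
#' delta(c_i, c_j)` with strengths `k_i` and resolution `gamma` scaling the
#' configuration null model. Diagonal entries of the adjacency, when present
#' (aggregated graphs), are counted as written.
#'
#' @param graph An [SnnGraph-class] or a symmetric (sparse) adjacency matrix.
#' @param labels Integer community labels, one per node.
#' @param resolution Resolution gamma (default 0.5).
#' @return Modularity Q.
#' @export
graphModularity <- function(graph, labels, resolution = 0.5) {
  a <- if (is(graph, "SnnGraph")) snnAdjacency(graph) else
    as(as(graph, "generalMatrix"), "CsparseMatrix")
  m2 <- sum(a)
  if (m2 == 0) return(0)
  labels <- as.integer(factor(labels))
  strength <- Matrix::rowSums(a)
  sTot <- rowsum(strength, labels)[, 1]
  memb <- Matrix::sparseMatrix(i = seq_along(labels), j = labels, x = 1,
                               dims = c(length(labels), max(labels)))
  inW <- sum(Matrix::diag(Matrix::t(memb) %*% a %*% memb))
  inW / m2 - resolution * sum((sTot / m2)^2)
}

#' Louvain community detection
#'
#' Greedy modularity optimization with a resolution parameter: repeated local
#' node moves (sweep order shuffled by `seed`, a move accepted only when it
#' improves Q by more than 1e-10) followed by graph aggregation, until no
#' pass improves Q. Cluster IDs are contiguous integers from 0, ordered by
#' decreasing cluster size (ties by the smallest member index). The per-pass
#' modularity trajectory is attached as attribute `"passModularity"` and is
#' non-decreasing by construction.
#'
#' @param graph An [SnnGraph-class] or symmetric sparse adjacency matrix.
#' @param resolution Resolution gamma (default 0.5).
#' @param seed Integer seed controlling the node sweep orders.
#' @param nRestarts Number of independent greedy runs (sweep orders derived
#'   from `seed`); the labeling with the highest final Q is returned. Greedy
#'   local moving can stall in a local optimum, so a handful of restarts
#'   makes small-graph optima reliable (default 8).
#' @return Integer vector of 0-based cluster labels, with attributes
#'   `"modularity"` (final Q) and `"passModularity"` (trajectory of the
#'   winning run).
#' @export
louvainCluster <- function(graph, resolution = 0.5, seed = 0L,
                           nRestarts = 8L) {
  a <- if (is(graph, "SnnGraph")) snnAdjacency(graph) else graph
  # symmetric sparse classes store one triangle only; the adjacency lists
  # need both
  a <- as(as(as(a, "generalMatrix"), "CsparseMatrix"), "dMatrix")
  n0 <- nrow(a)
  if (n0 == 0) stopf("empty graph")
  best <- NULL
  for (r in seq_len(max(1L, nRestarts))) {
    cand <- louvainOnce(a, resolution, deriveSeed(seed, paste0("sweep", r)))
    if (is.null(best) ||
        attr(cand, "modularity") > attr(best, "modularity") + 1e-12)
      best <- cand
  }
  best
}

louvainOnce <- function(a, resolution, seed) {
  n0 <- nrow(a)
  withSeed(seed, {
    labels0 <- seq_len(n0)          # node -> current community of its supernode
    nodeMap <- seq_len(n0)          # original node -> supernode
    passQ <- numeric(0)
    repeat {
      res <- louvainLocalPass(a, resolution)
      labels <- res$labels
      q <- graphModularity(a, labels, resolution)
      if (length(passQ) && q <= passQ[length(passQ)] + 1e-10 && !res$moved)
        break
      passQ <- c(passQ, q)
      nodeMap <- labels[nodeMap]
      if (!res$moved || max(labels) == nrow(a)) break
      # Aggregate: A'[c,d] = sum over i in c, j in d of A[i,j]
      memb <- Matrix::sparseMatrix(i = seq_len(nrow(a)), j = labels, x = 1,
                                   dims = c(nrow(a), max(labels)))
      a <- as(as(Matrix::t(memb) %*% a %*% memb, "generalMatrix"),
              "CsparseMatrix")
      if (nrow(a) == 1L) break
    }
    out <- relabelBySize(nodeMap)
    attr(out, "modularity") <- passQ[length(passQ)]
    attr(out, "passModularity") <- passQ
    out
  })
}

# One local-moving phase; returns contiguous 1-based labels and whether any
# node changed community.
louvainLocalPass <- function(a, resolution) {
  n <- nrow(a)
  m2 <- sum(a)
  strength <- Matrix::rowSums(a)
  selfW <- Matrix::diag(a)
  comm <- seq_len(n)
  sTot <- strength
  # adjacency lists excluding the diagonal
  aT <- as(a, "TsparseMatrix")
  keep <- aT@i != aT@j
  nbrList <- split(data.frame(j = aT@j[keep] + 1L, w = aT@x[keep]),
                   factor(aT@i[keep] + 1L, levels = seq_len(n)))
  moved <- FALSE
  if (m2 == 0)
    return(list(labels = comm, moved = FALSE))
  m <- m2 / 2
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (i in sample.int(n)) {
      nb <- nbrList[[i]]
      if (!nrow(nb)) next
      ci <- comm[i]
      wNb <- rowsum(nb$w, comm[nb$j])
      cand <- as.integer(rownames(wNb))
      wToOwn <- if (ci %in% cand) wNb[match(ci, cand), 1] else 0
      sTot[ci] <- sTot[ci] - strength[i]
      # Gain of joining community c relative to staying alone:
      # dQ(c) = w_ic/m - gamma * k_i * sTot_c / (2 m^2)
      gains <- wNb[, 1] / m -
        resolution * strength[i] * sTot[cand] / (2 * m^2)
      gainOwn <- wToOwn / m -
        resolution * strength[i] * sTot[ci] / (2 * m^2)
      best <- which.max(gains)
      if (length(best) && gains[best] > gainOwn + 1e-10) {
        comm[i] <- cand[best]
        sTot[cand[best]] <- sTot[cand[best]] + strength[i]
        moved <- TRUE
        improved <- TRUE
      } else {
        sTot[ci] <- sTot[ci] + strength[i]
      }
    }
  }
  list(labels = as.integer(factor(comm)), moved = moved)
}

# Contiguous 0-based labels ordered by decreasing size, ties by smallest
# member index.
relabelBySize <- function(labels) {
  labels <- as.integer(factor(labels))
  sizes <- tabulate(labels)
  firstIdx <- vapply(seq_along(sizes), function(c) which(labels == c)[1], 0L)
  rankOf <- integer(length(sizes))
  rankOf[order(-sizes, firstIdx)] <- seq_along(sizes) - 1L
  rankOf[labels]
}
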