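#' Rank genes by average log2 fold change
#'
#' Descending by `avg_log2fc`, ties broken by gene ID ascending; the result
#' is invariant to the input row order.
#'
#' @param table Marker table with `gene` and `avg_log2fc` columns.
#' @return Named numeric vector of ranking metrics, sorted descending.
#' @export
rankByLog2fc <- function(table) {
  if (!nrow(table)) stopf("marker table is empty")
  ord <- order(-table$avg_log2fc, table$gene)
  stats::setNames(as.numeric(table$avg_log2fc[ord]),
                  as.character(table$gene[ord]))
}

#' GSEA enrichment score
#'
#' Walks the ranked list from top to bottom: a hit increments the running sum
#' by `|r_i|^p / N_R` (with `N_R` the sum of `|r|^p` over hits), a miss
#' decrements it by `1/(N - N_H)`. The enrichment score is the running-sum
#' value of maximum absolute deviation from zero (first occurrence on ties).
#' With `weightP = 0` this reduces to the classic Kolmogorov-Smirnov running
#' statistic. When every hit metric is zero the hit increments fall back to
#' the unweighted `1/N_H`.
#'
#' @param ranked Named numeric metric vector sorted descending (a
#'   [rankByLog2fc()] result).
#' @param geneSet Character vector of gene IDs; its intersection with the
#'   ranked genes must be non-empty and proper.
#' @param weightP Metric weight exponent p (default 1).
#' @return List with `es` and the `running` sum curve (length N).
#' @export
enrichmentScore <- function(ranked, geneSet, weightP = 1) {
  N <- length(ranked)
  hit <- names(ranked) %in% geneSet
  nH <- sum(hit)
  if (nH == 0L) stopf("gene set shares no gene with the ranked list")
  if (nH == N) stopf("gene set covers the whole ranked list")
  w <- abs(ranked)^weightP
  nR <- sum(w[hit])
  inc <- if (nR > 0) w / nR else rep(1 / nH, N)
  step <- ifelse(hit, inc, -1 / (N - nH))
  running <- cumsum(step)
  es <- running[which.max(abs(running))]
  list(es = es, running = running)
}

#' Pre-ranked GSEA with gene-set permutation
#'
#' For each gene set, the observed enrichment score is compared against a
#' null of `nPerm` random gene sets of identical size drawn without
#' replacement from the ranked genes. The permutation p-value uses the
#' add-one estimator restricted to same-sign null scores:
#' `p = (1 + #{null same sign, |null| >= |obs|}) / (1 + #{null same sign})`.
#' NES divides the observed score by the mean magnitude of same-sign null
#' scores; null scores are normalized the same way (per set, per sign) and
#' pooled across sets for the FDR:
#' `q = (fraction of pooled null NES at least as extreme) /
#' (fraction of observed NES at least as extreme)`, per sign, clipped to
#' \[0, 1\] and made monotone over the observed extremeness ordering.
#'
#' The null permutes gene-set membership, not phenotype labels — the only
#' coherent scheme when the input is a single pre-ranked list.
#'
#' @param ranked Named metric vector sorted descending.
#' @param collection Named list of gene sets ([readGmt()] output). Sets
#'   sharing no gene with the ranked list are dropped with a warning.
#' @param nPerm Number of permutations (default 1000, >= 1).
#' @param seed Integer seed.
#' @param weightP Metric weight exponent (default 1).
#' @param qThreshold Significance threshold on `fdr_q` (default 0.05).
#' @return Data.frame with one row per retained set: `set, size, es, nes,
#'   p_perm, fdr_q, significant`, in collection order.
#' @export
prerankedGsea <- function(ranked, collection, nPerm = 1000, seed = 0L,
                          weightP = 1, qThreshold = 0.05) {
  if (nPerm < 1) stopf("nPerm must be at least 1")
  if (!length(collection)) stopf("empty gene-set collection")
  genes <- names(ranked)
  sizes <- vapply(collection, function(s) sum(genes %in% s), 0L)
  drop <- sizes == 0L | sizes == length(genes)
  if (any(drop)) {
    warnf("dropping %d gene set(s) with empty or full overlap: %s",
          sum(drop), paste(names(collection)[drop], collapse = ", "))
    collection <- collection[!drop]
    sizes <- sizes[!drop]
  }
  if (!length(collection)) stopf("no gene set overlaps the ranked list")
  withSeed(seed, {
    obsEs <- vapply(collection, function(s)
      enrichmentScore(ranked, s, weightP)$es, 0)
    uniqSizes <- sort(unique(sizes))
    nullBySize <- lapply(uniqSizes, function(sz) {
      vapply(seq_len(nPerm), function(i)
        enrichmentScore(ranked, sample(genes, sz), weightP)$es, 0)
    })
    names(nullBySize) <- as.character(uniqSizes)

    pPerm <- numeric(length(collection))
    nes <- numeric(length(collection))
    nullNesPool <- list()
    for (k in seq_along(collection)) {
      nulls <- nullBySize[[as.character(sizes[k])]]
      sgn <- if (obsEs[k] >= 0) 1 else -1
      same <- if (sgn > 0) nulls[nulls >= 0] else nulls[nulls < 0]
      pPerm[k] <- (1 + sum(abs(same) >= abs(obsEs[k]))) / (1 + length(same))
      meanPos <- mean(nulls[nulls >= 0])
      meanNeg <- mean(abs(nulls[nulls < 0]))
      nes[k] <- if (sgn > 0) {
        if (is.finite(meanPos) && meanPos > 0) obsEs[k] / meanPos else 0
      } else {
        if (is.finite(meanNeg) && meanNeg > 0) obsEs[k] / meanNeg else 0
      }
      nn <- numeric(length(nulls))
      posIdx <- nulls >= 0
      nn[posIdx] <- if (is.finite(meanPos) && meanPos > 0)
        nulls[posIdx] / meanPos else 0
      nn[!posIdx] <- if (is.finite(meanNeg) && meanNeg > 0)
        nulls[!posIdx] / meanNeg else 0
      nullNesPool[[k]] <- nn
    }
    pool <- unlist(nullNesPool)
    fdr <- numeric(length(collection))
    for (sgn in c(1, -1)) {
      idx <- if (sgn > 0) which(nes >= 0) else which(nes < 0)
      if (!length(idx)) next
      poolSide <- if (sgn > 0) pool[pool >= 0] else pool[pool < 0]
      obsSide <- nes[idx]
      for (k in seq_along(idx)) {
        v <- obsSide[k]
        num <- if (length(poolSide))
          mean(abs(poolSide) >= abs(v)) else 0
        den <- mean(abs(obsSide) >= abs(v))
        fdr[idx[k]] <- min(1, if (den > 0) num / den else 1)
      }
      # monotone: a more extreme NES never gets a larger q
      ord <- order(-abs(obsSide))
      fdr[idx[ord]] <- rev(cummin(rev(fdr[idx[ord]])))
    }
    data.frame(set = names(collection), size = as.integer(sizes),
               es = obsEs, nes = nes, p_perm = pPerm, fdr_q = fdr,
               significant = fdr < qThreshold, row.names = NULL)
  })
}
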