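---
title: "Cross-tissue pericyte marker discovery: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-tissue pericyte marker discovery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pericyteMarkers)
```

## The problem

Pericytes are mural cells that wrap capillaries and contact endothelial
cells. No single surface marker separates them reliably from the other mural
populations — smooth muscle cells, fibroblasts, myofibroblasts — because the
two traditionally accepted markers, *Cspg4* (NG2) and *Pdgfrb*, are each
expressed by those confusable neighbors as well. A practical way out is to
demand **co-expression**: within an unsupervised cluster that is visibly
enriched for dual-positive cells, keep only the cells with raw count > 0 for
*both* markers ("stringent pericytes"), then ask which genes are expressed in
almost all of those cells and almost nowhere else in the tissue. Done per
tissue, this yields tissue-specific candidate marker panels that can be
compared across organs.

This package implements that analysis as a tested pipeline over
`SingleCellExperiment` objects, together with a synthetic-data generator
that plants known markers so every stage can be validated against ground
truth.

## Pipeline stages

### Normalization

`logNormalize()` computes `x = ln(1 + c * S / L)` with library size `L`
(column sum) and scale factor `S = 10,000` — the droplet-data convention.
Natural log with pseudocount 1 keeps zeros at zero and preserves sparsity.
Cells with zero library size are an error (they cannot be normalized) and
are reported by barcode.

### Variable genes (VST)

`selectHvgVst()` ranks genes by the variance of standardized counts: per
gene, the observed mean and variance of raw counts; a loess fit (span 0.3,
degree 2, the defaults the variance-stabilizing-transformation method is
known by) of `log10(variance)` on `log10(mean)` over genes with positive
variance gives an expected standard deviation; counts standardized by it are
clipped at `±sqrt(n_cells)` and the gene's score is the sample variance of
the clipped values. Clipping keeps a handful of jackpot cells from dominating
the ranking. Constant genes score zero. Ties are broken by gene ID so the
selection is reproducible. The default of 2,000 genes is capped at the
universe size with a warning.

### Scaling and PCA

`scaleAndPca()` z-scores each variable gene over cells, clips at ±10 (the droplet-toolkit convention for scaled data), and takes the SVD of the resulting matrix via the smaller Gram
matrix. Two deterministic conventions: components are ordered by
non-increasing explained variance, and each component's sign is fixed so its
largest-magnitude gene loading is positive — linear-algebra backends differ
in sign, and downstream clustering should not. Per-tissue PC counts default
to 35, with kidney at 45 and bladder at 30, reflecting where the variance
profiles of those tissues flatten.

### SNN graph and Louvain clustering

`knnNeighbors()` finds exact Euclidean k-nearest neighbors in PC space
(k = 20 by default; the neighbor set includes the cell itself, and distance
ties break to the lower cell index). `snnJaccard()` weights cell pairs by the
Jaccard similarity of their neighbor sets and prunes weights below 1/15.
Both defaults are the common droplet-toolkit values; they are exposed as
parameters and documented as defaults rather than tuned per dataset.

`louvainCluster()` maximizes modularity
`Q = (1/2m) * sum_ij [A_ij - gamma * k_i k_j / (2m)] * delta(c_i, c_j)`
with the resolution `gamma` (default 0.5) scaling the configuration null
model. The implementation is the classic two-phase greedy: local moves in a
seed-shuffled sweep order, accepted only when they improve Q by more than
1e-10, then graph aggregation, repeated until no pass improves Q. Greedy
local moving can stall in local optima — on small graphs measurably below
the exhaustive-partition optimum — so the default runs 8 restarts with sweep
orders derived from the seed and keeps the best final Q; the result is still
fully deterministic given the seed. Cluster IDs are contiguous integers from
0 ordered by decreasing size. The per-pass modularity trajectory is exposed
(`attr(labels, "passModularity")`) and is non-decreasing by construction.

### Gating stringent pericytes

"Expressing" means raw count > 0 throughout — magnitude thresholds are
deliberately avoided because droplet counts for these markers are shallow,
and detection is the robust notion at that depth. "Enriched for
dual-positive cells" is qualitative on its face;
`findEnrichedClusters()` operationalizes it with two numeric conditions: the
cluster's dual-positive fraction must reach an absolute floor
(`minDualFraction = 0.05`, set below the ~10% stringent proportions seen in
the least dual-positive real tissues, so a comparable cluster qualifies)
and exceed `foldOverGlobal = 5` times the tissue-wide dual-positive
fraction (so diffuse leak cannot qualify a cluster in a tissue where the
markers are broadly detected). Several clusters may qualify and are pooled for gating — in real tissues
the mural compartment regularly splits across two clusters. `gateStringent()` then keeps
dual-positive cells inside enriched clusters; `gateSummary()` reports per
tissue `n_stringent`, enriched-cluster cell count and their ratio, and the
written summary table carries a total row so the cross-tissue bookkeeping
identity (total = sum of per-tissue counts) is explicit.

### Marker statistics

`computeMarkerTable()` tests every gene detected in at least 3 cells (rank
tests on fewer are degenerate; the threshold is exposed) with a two-sided
Wilcoxon rank-sum test of stringent pericytes against **all** other cells of
the tissue — including non-stringent cells inside enriched clusters, which
makes the contrast conservative for mural-adjacent genes.
`wilcoxonTest()` provides two modes: exact enumeration of all
`choose(n+m, n)` assignments (used in validation; feasible to n+m = 12) and
the tie-corrected normal approximation with continuity correction 0.5 (used
in the pipeline, where groups always have at least 3 cells). When every
value is tied the p-value is 1 by convention. p-values are adjusted by
Benjamini–Hochberg step-up (`bhAdjust()`), the standard FDR control for
marker screens.

The fold change is
`avg_log2fc = log2((mean(expm1(x_str)) + 1) / (mean(expm1(x_oth)) + 1))` —
de-logged normalized means with pseudocount 1 on both sides, which is
symmetric and exactly zero for equal means.

Expression fractions come from raw counts: `pct1` (stringent cells),
`pct2` (all other cells), and `pct3` — the maximum expressing fraction
across clusters *outside* the enriched set (`pct3PerGene()`), which exposes
markers that are clean against the tissue average but concentrated in one
other cluster. `selectMarkers()` applies strict inequalities (more than 80%, less than 5%,
below 0.05, below 10%):
`selected` requires `p_adj < 0.05`, `pct1 > 0.80`, `pct2 < 0.05`;
`high_specificity` additionally `pct3 < 0.10`. `pct3` is reported for all
tested genes, not only selected ones. `crossTissueVenn()` assigns every gene
in the union of the per-tissue selected sets to exactly one membership
pattern; pattern sizes sum to the union size by construction.

### Pre-ranked GSEA

`rankByLog2fc()` sorts the tested genes by descending fold change (ties by
gene ID). `enrichmentScore()` runs the weighted running-sum statistic:
hits add `|r|^p / N_R` (p = 1, the method's standard weighting), misses
subtract
`1/(N - N_H)`; the score is the extreme deviation of the running sum. With
p = 0 it reduces to the classic Kolmogorov–Smirnov form, which the tests
check directly.

`prerankedGsea()` estimates significance by **gene-set permutation**:
`nPerm` random same-size sets drawn from the ranked genes. Phenotype-label
scrambling — the other classic GSEA null — is undefined for a single
pre-ranked list, since no per-sample labels remain to scramble; gene-set
permutation is the only coherent choice for pre-ranked input, and q-values
under the two nulls are not comparable. The p-value uses the add-one
estimator restricted to same-sign null scores (never exactly zero, floor
`1/(nPerm+1)`); NES divides the observed score by the mean magnitude of
same-sign null scores; the FDR q pools the per-set normalized null scores
and compares, per sign, the fraction of null NES at least as extreme against
the fraction of observed NES at least as extreme, clipped to [0, 1] and made
monotone (a more extreme set never reports a larger q). Sets that share no
gene with the ranking are dropped with a warning.

### Spatial co-localization

`clusterSpots()` reuses the single-cell stages on a spot×gene matrix.
`designatePericyteSpots()` applies the same dual-positive enrichment rule at
cluster level and returns *all* spots of qualifying clusters — designation
is a cluster property: a qualifying cluster contributes all of its spots,
and multiple qualifying clusters are pooled.
`spotSets()` is the strict count > 0 rule per gene. `vennColocalize()`
reports all seven regions of the three-set partition (two marker spot sets
and the pericyte spot set). Overlap percentages are only meaningful with a stated base, so all
percentages here use |pericyte spots| as the explicit denominator
(`pct_overlap_A = 100 |A∩P| / |P|`, etc.). Array coordinates are treated as
a rectangular grid with 4-connectivity; hexagonal offsets are out of scope.

## The synthetic-data generator

`simulateTissueCounts()` emulates the statistical structure the pipeline
assumes, not any particular tissue's biology:

* counts are negative binomial on (cell-type mean × lognormal library
  factor) with a dispersion shared across genes — the standard overdispersed
  droplet model, simple to invert in tests;
* each cell type carries a private 30-gene program (mean 3 vs 0.05), which
  is what makes the populations separable in PC space;
* pericytes are dual-positive for the canonical pair with probability
  `dualPosRate` (default 0.9; the remainder express one marker at random),
  and smooth-muscle cells express only the second canonical marker with
  probability 0.8 — the confusable mural population;
* planted markers are controlled by Bernoulli detection gates: probability
  `piIn` (default 0.95) in pericytes of the target tissue, `piOut` (default
  0.01) everywhere else; decoys use 0.5, deliberately between the pct1 and
  pct2 thresholds so they are significant by p-value yet must be rejected by
  the expression-fraction filters. On-state counts are drawn from a
  unit-shifted negative binomial (`1 + NB(mu-1)`), so the gate probability
  *is* the expression fraction — plain NB-mean gating would re-introduce
  zeros on gated-on cells and decouple the gates from the pct statistics the
  pipeline filters on;
* shared markers are planted in designated tissue pairs (the first pair of
  the default four-tissue layout mirrors a lung∩heart marker), and
  per-tissue seeds derive from the master seed plus a stable label hash, so
  tissues are independent yet reproducible;
* the spatial section plants 1-wide self-avoiding 4-connected artery paths
  (smooth-muscle marker), scattered capillary spots (endothelial marker),
  pericyte spots adjacent to capillaries (canonical pair plus the two
  co-localization markers with probabilities 0.75/0.70), and background;
  region marker genes are expressed only in their own region, and each
  region has a private program so spot clustering can recover it.

Defaults describe the validation conditions: four tissues of 500 cells over
a 1,200-gene universe, 10 planted markers and 4 decoys per tissue, 4 shared
markers.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: donor/batch structure (integration is out of
scope), doublets, ambient RNA, gene–gene correlation beyond the block
programs, hexagonal spatial geometry, and realistic mean–variance curvature
across the whole transcriptome. Recovery rates on this generator validate
the machinery (gating arithmetic, rank tests, fraction filters, permutation
calibration), not field performance on atlas data.

## Numerical choices and degenerate inputs

* Strict inequalities at every marker threshold; boundary values are
  excluded by design.
* Wilcoxon with all values tied reports p = 1; variance underflow is caught.
* BH is implemented as the step-up suffix minimum, clipped at 1, and checked
  against `stats::p.adjust` in the tests.
* Louvain accepts a move only above a 1e-10 modularity gain; ties keep the
  current community.
* PCA of a rank-deficient matrix zero-pads components beyond the rank;
  constant genes scale to zero rows instead of NaN.
* Empty gate results are a warning plus an empty set, and the pipeline skips
  that tissue's downstream stages, flags the run partial, and continues with
  the other tissues.
* Every random stage takes an explicit seed; the pipeline derives per-stage,
  per-tissue seeds from the master seed, and rerunning a configuration
  byte-identically reproduces all result tables.

## Problem sizes used in validation

The test suite and the acceptance script run the generator at desk scale,
chosen so the statistical assertions have power while the whole suite stays
fast: four tissues of 350–600 cells over 800–1,200 genes for end-to-end
marker recovery; 2,000 replicate null genes for type-I calibration; 200
random gene sets at 400–1,000 permutations for GSEA calibration; 40×40 spot
grids for the spatial stage; exhaustive oracles (partition enumeration,
rank-sum enumeration) up to 8 nodes and 12 observations.

## Known limitations

* The enrichment rule's two constants operationalize a qualitative notion
  of enrichment; on tissues where pericytes shade into
  smooth muscle continuously, cluster-level gating is sensitive to the
  clustering resolution.
* Gene-set permutation answers a different null than sample permutation;
  q-values are not comparable across the two schemes.
* The mouse-to-human ortholog mapping is symbol case conversion only
  (`mouseToHumanSymbols()`); genuine homology mapping needs an external
  resource.
* Exact nearest-neighbor search is quadratic in cells; the pipeline targets
  desk-scale matrices, not atlas-scale ones.
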