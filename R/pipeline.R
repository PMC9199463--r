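#' Default pipeline configuration
#'
#' Returns the full default configuration as a named list. Tissue-level PC
#' counts default to 35, with kidney at 45 and bladder at 30; clustering uses
#' k = 20 nearest neighbors, SNN pruning at 1/15 and Louvain resolution 0.5;
#' marker selection uses adjusted p < 0.05, pct1 > 0.80, pct2 < 0.05 and
#' pct3 < 0.10.
#'
#' @param simulation Optional [SimConfig-class] (simulation-backed run).
#' @param inputBundles Optional named list tissue -> MTX bundle directory.
#' @param seed Master seed.
#' @return A named list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(simulation = NULL, inputBundles = NULL, seed = 1L) {
  structure(list(
    simulation = simulation,
    inputBundles = inputBundles,
    scaleFactor = 1e4,
    nHvg = 2000L,
    nPcsDefault = 35L,
    nPcsPerTissue = list(kidney = 45L, bladder = 30L),
    k = 20L,
    prune = 1 / 15,
    resolution = 0.5,
    gate = list(markerA = "Cspg4", markerB = "Pdgfrb",
                minDualFraction = 0.05, foldOverGlobal = 5),
    markers = list(alpha = 0.05, pct1Min = 0.80, pct2Max = 0.05,
                   pct3Max = 0.10, minCells = 3L),
    gsea = list(gmt = NULL, nPerm = 1000L, q = 0.05),
    spatial = list(enabled = FALSE, grid = c(48L, 48L)),
    seed = as.integer(seed)
  ), class = "pipelineConfig")
}

#' Validate a pipeline configuration
#'
#' Accepts a path to a JSON or YAML file or a plain list; injects defaults
#' for missing keys, rejects unknown keys, and reports all type/range
#' violations at once.
#'
#' @param config Path (`.json`, `.yaml`/`.yml`) or list.
#' @return A validated `pipelineConfig` list.
#' @export
validateConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stopf("the yaml package is required for YAML configs")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is(config, "SimConfig"))
    config <- list(simulation = config)
  stopifnot(is.list(config))
  defaults <- pipelineConfig()
  errors <- character(0)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    errors <- c(errors, sprintf("unknown key(s): %s",
                                paste(unknown, collapse = ", ")))
  for (grp in c("gate", "markers", "gsea", "spatial")) {
    if (!is.null(config[[grp]])) {
      bad <- setdiff(names(config[[grp]]), names(defaults[[grp]]))
      if (length(bad))
        errors <- c(errors, sprintf("unknown key(s) in %s: %s", grp,
                                    paste(bad, collapse = ", ")))
      config[[grp]] <- utils::modifyList(defaults[[grp]],
                                         config[[grp]][setdiff(names(config[[grp]]), bad)])
    }
  }
  merged <- utils::modifyList(defaults, config[!names(config) %in% unknown])
  checkRange <- function(value, name, lo, hi, loOpen = FALSE) {
    if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
        value < lo || value > hi || (loOpen && value <= lo))
      errors <<- c(errors, sprintf("%s must be a number in %s%g, %g]",
                                   name, if (loOpen) "(" else "[", lo, hi))
  }
  checkRange(merged$scaleFactor, "scaleFactor", 0, Inf, loOpen = TRUE)
  checkRange(merged$nHvg, "nHvg", 1, Inf)
  checkRange(merged$nPcsDefault, "nPcsDefault", 1, Inf)
  checkRange(merged$k, "k", 1, Inf)
  checkRange(merged$prune, "prune", 0, 1)
  checkRange(merged$resolution, "resolution", 0, Inf, loOpen = TRUE)
  checkRange(merged$markers$alpha, "markers$alpha", 0, 1)
  checkRange(merged$markers$pct1Min, "markers$pct1Min", 0, 1)
  checkRange(merged$markers$pct2Max, "markers$pct2Max", 0, 1)
  checkRange(merged$markers$pct3Max, "markers$pct3Max", 0, 1)
  checkRange(merged$gsea$nPerm, "gsea$nPerm", 1, Inf)
  checkRange(merged$gsea$q, "gsea$q", 0, 1)
  checkRange(merged$gate$minDualFraction, "gate$minDualFraction", 0, 1,
             loOpen = TRUE)
  checkRange(merged$gate$foldOverGlobal, "gate$foldOverGlobal", 0, Inf,
             loOpen = TRUE)
  if (is.null(merged$seed) || is.na(suppressWarnings(as.integer(merged$seed))))
    errors <- c(errors, "seed must be an integer")
  if (!is.null(merged$nPcsPerTissue) && !is.list(merged$nPcsPerTissue))
    merged$nPcsPerTissue <- as.list(merged$nPcsPerTissue)
  if (length(errors))
    stopf("invalid configuration:\n- %s", paste(errors, collapse = "\n- "))
  merged$seed <- as.integer(merged$seed)
  class(merged) <- "pipelineConfig"
  merged
}

nPcsFor <- function(config, tissue) {
  as.integer(config$nPcsPerTissue[[tissue]] %||% config$nPcsDefault)
}

#' Run the full marker-discovery pipeline
#'
#' Per tissue: log-normalize, select variable genes, PCA, SNN-Louvain
#' clustering, stringent-pericyte gating, Wilcoxon marker table and
#' (optionally) pre-ranked GSEA; then the cross-tissue Venn partition of the
#' selected marker sets, the pooled gate summary, and an optional spatial
#' stage. All result tables are written as TSV under `outputDir`, along with
#' a JSON run manifest (configuration, seed, package version, per-stage row
#' counts) and a timestamped log. Tissues whose gate finds no enriched
#' cluster are skipped past gating with a warning; the run is then flagged
#' partial but other tissues proceed. Fully deterministic given the seed.
#'
#' @param config A `pipelineConfig` list (see [pipelineConfig()],
#'   [validateConfig()]) with either `simulation` or `inputBundles` set.
#' @param outputDir Output directory (created; must be empty or absent).
#' @return Invisibly, a list with `outputDir`, `manifest`, and per-tissue
#'   results (`clusters`, `gate`, `markers`, `gsea`).
#' @export
runPipeline <- function(config, outputDir) {
  config <- validateConfig(unclass(config))
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(outputDir, "run.log")
  logMsg <- function(fmt, ...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                sprintf(fmt, ...)),
        file = logPath, append = TRUE)
  }
  logMsg("pipeline start (seed %d)", config$seed)
  if (!is.null(config$simulation)) {
    sim <- config$simulation
    if (!is(sim, "SimConfig")) sim <- do.call(simConfig, as.list(sim))
    tissues <- simulateMultiTissue(sim, seed = sim@seed)
    gateP <- gateParams(sim@canonicalPair[1], sim@canonicalPair[2],
                        config$gate$minDualFraction,
                        config$gate$foldOverGlobal)
  } else if (!is.null(config$inputBundles)) {
    tissues <- lapply(names(config$inputBundles), function(t)
      readMtxBundle(config$inputBundles[[t]], tissue = t))
    names(tissues) <- names(config$inputBundles)
    gateP <- gateParams(config$gate$markerA, config$gate$markerB,
                        config$gate$minDualFraction,
                        config$gate$foldOverGlobal)
  } else stopf("config must provide either 'simulation' or 'inputBundles'")
  gmtSets <- if (!is.null(config$gsea$gmt)) readGmt(config$gsea$gmt)
  results <- list()
  summaries <- list()
  markerSets <- list()
  partial <- FALSE
  stageCounts <- list()
  for (t in names(tissues)) {
    sce <- tissues[[t]]
    logMsg("[%s] %d cells, %d genes", t, ncol(sce), nrow(sce))
    sce <- logNormalize(sce, config$scaleFactor)
    hvgs <- suppressWarnings(selectHvgVst(sce, min(config$nHvg, nrow(sce))))
    nPcs <- min(nPcsFor(config, t), length(hvgs) - 1L, ncol(sce) - 1L)
    emb <- scaleAndPca(sce, hvgs, nPcs)
    nbrs <- knnNeighbors(emb, min(config$k, ncol(sce) - 1L))
    graph <- snnJaccard(nbrs, config$prune)
    labels <- louvainCluster(graph, config$resolution,
                             seed = deriveSeed(config$seed, paste0(t, ":louvain")))
    logMsg("[%s] %d clusters (Q=%.4f)", t, length(unique(labels)),
           attr(labels, "modularity"))
    gate <- tryCatch(
      withCallingHandlers(
        gateCells(sce, labels, gateP, tissue = t),
        warning = function(w) {
          logMsg("[%s] gate warning: %s", t, conditionMessage(w))
          invokeRestart("muffleWarning")
        }),
      error = function(e) stopf("stage gate failed for tissue %s: %s", t,
                                conditionMessage(e)))
    summaries[[t]] <- gateSummaryTable(gate)
    res <- list(clusters = labels, gate = gate, markers = NULL, gsea = NULL)
    if (!length(enrichedClusters(gate)) || sum(stringentMask(gate)) < 3L) {
      logMsg("[%s] gate empty or too small; skipping markers/GSEA", t)
      partial <- TRUE
    } else {
      tab <- tryCatch(
        computeMarkerTable(sce, stringentMask(gate), labels,
                           enrichedClusters(gate),
                           minCells = config$markers$minCells),
        error = function(e) stopf("stage markers failed for tissue %s: %s",
                                  t, conditionMessage(e)))
      tab <- selectMarkers(tab, config$markers$alpha, config$markers$pct1Min,
                           config$markers$pct2Max, config$markers$pct3Max)
      writeMarkerTable(tab, file.path(outputDir,
                                      sprintf("markers_%s.tsv", t)))
      markerSets[[t]] <- tab$gene[tab$selected]
      res$markers <- tab
      stageCounts[[paste0("markers_", t)]] <- nrow(tab)
      logMsg("[%s] %d genes tested, %d selected, %d high-specificity",
             t, nrow(tab), sum(tab$selected), sum(tab$high_specificity))
      if (!is.null(gmtSets)) {
        ranked <- rankByLog2fc(tab)
        gs <- tryCatch(
          suppressWarnings(
            prerankedGsea(ranked, gmtSets, nPerm = config$gsea$nPerm,
                          seed = deriveSeed(config$seed, paste0(t, ":gsea")),
                          qThreshold = config$gsea$q)),
          error = function(e) stopf("stage gsea failed for tissue %s: %s",
                                    t, conditionMessage(e)))
        writeGseaResults(gs, file.path(outputDir, sprintf("gsea_%s.tsv", t)))
        res$gsea <- gs
        stageCounts[[paste0("gsea_", t)]] <- nrow(gs)
        logMsg("[%s] GSEA: %d/%d sets significant", t, sum(gs$significant),
               nrow(gs))
      }
    }
    results[[t]] <- res
  }
  gateTable <- do.call(rbind, summaries)
  writeGateSummary(gateTable, file.path(outputDir, "gate_summary.tsv"))
  stageCounts[["gate_summary"]] <- nrow(gateTable)
  venn <- NULL
  if (length(markerSets) >= 2L) {
    venn <- crossTissueVenn(markerSets)
    writeVennResult(venn, file.path(outputDir, "marker_venn.tsv"))
    stageCounts[["marker_venn"]] <- nrow(venn)
  }
  spatialRes <- NULL
  if (isTRUE(config$spatial$enabled)) {
    sim <- config$simulation
    if (!is(sim, "SimConfig")) sim <- do.call(simConfig, as.list(sim))
    spatialRes <- runSpatialStage(sim, config, outputDir,
                                  seed = deriveSeed(config$seed, "spatial"))
    stageCounts[["spatial_venn"]] <- 7L
    logMsg("spatial stage complete: %d pericyte spots",
           length(spatialRes$pericyteSpots))
  }
  manifest <- list(
    package = "pericyteMarkers",
    version = as.character(utils::packageVersion("pericyteMarkers")),
    seed = config$seed,
    tissues = names(tissues),
    partial = partial,
    stageRowCounts = stageCounts,
    config = configForManifest(config))
  jsonlite::write_json(manifest, file.path(outputDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  logMsg("pipeline done (partial=%s)", partial)
  invisible(list(outputDir = outputDir, manifest = manifest,
                 results = results, gateSummaries = gateTable, venn = venn,
                 spatial = spatialRes))
}

runSpatialStage <- function(sim, config, outputDir, seed) {
  spots <- simulateSpatialSection(sim, grid = config$spatial$grid, seed = seed)
  labels <- clusterSpots(spots, seed = deriveSeed(seed, "spotlouvain"),
                         resolution = config$resolution, k = config$k,
                         prune = config$prune,
                         scaleFactor = config$scaleFactor)
  gateP <- gateParams(sim@canonicalPair[1], sim@canonicalPair[2],
                      config$gate$minDualFraction, config$gate$foldOverGlobal)
  peri <- suppressWarnings(designatePericyteSpots(spots, labels, gateP))
  setA <- spotSets(spots, "Higd1b")
  setB <- spotSets(spots, "Notch3")
  venn <- vennColocalize(setA, setB, peri)
  df <- data.frame(region = names(vennRegionSizes(venn)),
                   n = as.integer(vennRegionSizes(venn)))
  writeTsv(df, file.path(outputDir, "spatial_venn.tsv"), c("region", "n"))
  writeLines(sort(peri), file.path(outputDir, "spatial_pericyte_spots.tsv"))
  list(spots = spots, labels = labels, pericyteSpots = peri, venn = venn)
}

# JSON-serializable echo of the configuration.
configForManifest <- function(config) {
  out <- unclass(config)
  if (is(out$simulation, "SimConfig")) {
    s <- out$simulation
    out$simulation <- list(
      nTissues = s@nTissues, tissueNames = s@tissueNames, nCells = s@nCells,
      nGenes = s@nGenes,
      cellTypeProportions = as.list(s@cellTypeProportions),
      canonicalPair = s@canonicalPair,
      nPlantedMarkersPerTissue = s@nPlantedMarkersPerTissue,
      nSharedMarkers = s@nSharedMarkers,
      nDecoysPerTissue = s@nDecoysPerTissue,
      piIn = s@piIn, piOut = s@piOut, decoyPiIn = s@decoyPiIn,
      dualPosRate = s@dualPosRate, nbDispersion = s@nbDispersion,
      libsizeLognormal = s@libsizeLognormal, seed = s@seed)
  }
  out
}
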