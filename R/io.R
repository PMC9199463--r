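#' @importFrom Matrix readMM sparseMatrix t colSums rowSums
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
#' @importFrom SingleCellExperiment SingleCellExperiment
#' @importFrom SummarizedExperiment assay assays colData rowData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Read a Matrix Market count bundle
#'
#' Reads a droplet-style count bundle: `matrix.mtx` (coordinate integer
#' general, genes as rows, 1-based indices in the file), `features.tsv`
#' (gene IDs in the first column, optional symbol column) and `barcodes.tsv`.
#' Malformed input is rejected with an error naming the offending file
#' (and line, where a line is identifiable) rather than silently coerced.
#'
#' @param directory Path containing `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv`.
#' @param tissue Tissue label attached to the cells (default: directory name).
#' @return A [SingleCellExperiment][SingleCellExperiment::SingleCellExperiment]
#'   with a `counts` assay (sparse, genes x cells) and `colData$tissue`.
#' @seealso [writeMtxBundle()]
#' @export
readMtxBundle <- function(directory, tissue = basename(directory)) {
  paths <- file.path(directory, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  names(paths) <- basename(paths)
  for (p in paths) {
    if (!file.exists(p)) stopf("missing file: %s", p)
  }
  mtx <- paths[["matrix.mtx"]]
  header <- readLines(mtx, n = 1L)
  if (!grepl("^%%MatrixMarket[ \t]+matrix[ \t]+coordinate[ \t]+integer[ \t]+general[ \t]*$",
             header))
    stopf("%s line 1: expected header '%%%%MatrixMarket matrix coordinate integer general', got '%s'",
          mtx, header)
  m <- tryCatch(Matrix::readMM(mtx),
                error = function(e) stopf("%s: %s", mtx, conditionMessage(e)))
  m <- as(as(m, "CsparseMatrix"), "dMatrix")
  if (any(m@x != round(m@x)) || any(m@x < 0))
    stopf("%s: counts must be non-negative integers", mtx)
  genes <- readIdColumn(paths[["features.tsv"]])
  cells <- readIdColumn(paths[["barcodes.tsv"]])
  if (nrow(m) != length(genes))
    stopf("%s declares %d rows but %s has %d lines (dimension mismatch)",
          mtx, nrow(m), paths[["features.tsv"]], length(genes))
  if (ncol(m) != length(cells))
    stopf("%s declares %d columns but %s has %d lines (dimension mismatch)",
          mtx, ncol(m), paths[["barcodes.tsv"]], length(cells))
  dimnames(m) <- list(genes, cells)
  SingleCellExperiment(
    assays = list(counts = m),
    colData = DataFrame(tissue = rep(tissue, length(cells)),
                        row.names = cells))
}

# First tab-separated column of an ID file; errors name file and line.
readIdColumn <- function(path) {
  lines <- readLines(path)
  ids <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, character(1), 1L)
  bad <- which(is.na(ids) | ids == "")
  if (length(bad))
    stopf("%s line %d: empty identifier", path, bad[1])
  dup <- which(duplicated(ids))
  if (length(dup))
    stopf("%s line %d: duplicate identifier '%s'", path, dup[1], ids[dup[1]])
  ids
}

#' Write a Matrix Market count bundle
#'
#' Writes `matrix.mtx` (header `%%MatrixMarket matrix coordinate integer
#' general`, entries sorted by column then row, 1-based indices),
#' `features.tsv` and `barcodes.tsv`, readable back by [readMtxBundle()].
#'
#' @param counts A `SingleCellExperiment` with a `counts` assay, or a sparse
#'   genes x cells matrix with dimnames.
#' @param directory Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
writeMtxBundle <- function(counts, directory) {
  if (is(counts, "SummarizedExperiment")) counts <- assay(counts, "counts")
  counts <- as(as(counts, "CsparseMatrix"), "dMatrix")
  genes <- rownames(counts)
  cells <- colnames(counts)
  if (is.null(genes) || is.null(cells))
    stopf("counts must carry gene and barcode dimnames")
  if (anyDuplicated(genes) || anyDuplicated(cells))
    stopf("gene IDs and barcodes must be unique")
  for (ids in list(genes, cells)) {
    if (any(grepl("[\t\n]", ids)))
      stopf("identifiers must not contain tab or newline characters")
  }
  if (length(counts@x) && (any(counts@x != round(counts@x)) || any(counts@x < 0)))
    stopf("counts must be non-negative integers")
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  # dgCMatrix stores column-major, so (col, row)-sorted order is its native
  # order; emit triplets directly.
  i <- counts@i + 1L
  j <- rep.int(seq_len(ncol(counts)), diff(counts@p))
  keep <- counts@x != 0
  con <- file(file.path(directory, "matrix.mtx"), "w")
  on.exit(close(con))
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", nrow(counts), ncol(counts), sum(keep))),
             con)
  if (any(keep))
    writeLines(sprintf("%d %d %d", i[keep], j[keep],
                       as.integer(counts@x[keep])), con)
  writeLines(genes, file.path(directory, "features.tsv"))
  writeLines(cells, file.path(directory, "barcodes.tsv"))
  invisible(directory)
}

#' Read a GMT gene-set collection
#'
#' One set per line: name, description, then members, tab-separated.
#' Duplicate members within a set are dropped with a warning; duplicate set
#' names are an error; lines with fewer than three fields are an error with
#' the line number.
#'
#' @param path GMT file path.
#' @return Named list of character vectors of gene IDs; each element carries
#'   a `description` attribute.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stopf("%s: empty GMT file", path)
  sets <- list()
  for (k in seq_along(lines)) {
    f <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stopf("%s line %d: expected at least 3 tab-separated fields, got %d",
            path, k, length(f))
    nm <- f[1]
    if (nm %in% names(sets))
      stopf("%s line %d: duplicate gene-set name '%s'", path, k, nm)
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warnf("%s line %d: duplicate members in set '%s' deduplicated",
            path, k, nm)
      members <- unique(members)
    }
    if (!length(members)) stopf("%s line %d: set '%s' is empty", path, k, nm)
    attr(members, "description") <- f[2]
    sets[[nm]] <- members
  }
  sets
}

# Shared TSV writer: fixed column order supplied by caller, floats at six
# significant digits, no quoting (IDs are delimiter-checked on the way in).
writeTsv <- function(df, path, columns) {
  stopifnot(all(columns %in% names(df)))
  df <- df[, columns, drop = FALSE]
  out <- as.data.frame(lapply(df, signif6), optional = TRUE)
  names(out) <- columns
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a marker table as TSV
#'
#' Columns `gene, avg_log2fc, p, p_adj, pct1, pct2, pct3, selected,
#' high_specificity`; rows sorted by ascending adjusted p, ties by gene ID;
#' floats at six significant digits.
#'
#' @param table Marker table as returned by [computeMarkerTable()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
writeMarkerTable <- function(table, path) {
  df <- as.data.frame(table)
  df <- df[order(df$p_adj, df$gene), , drop = FALSE]
  writeTsv(df, path, c("gene", "avg_log2fc", "p", "p_adj",
                       "pct1", "pct2", "pct3", "selected", "high_specificity"))
}

#' Write gate summaries as TSV
#'
#' One row per tissue in input order plus a `total` row summing stringent and
#' enriched-cluster cell counts across tissues.
#'
#' @param summaries A data.frame of per-tissue gate summary rows (columns
#'   `tissue, n_stringent, n_enriched_cells, proportion`) or a list of
#'   [GateResult-class] objects.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
writeGateSummary <- function(summaries, path) {
  if (is.list(summaries) && !is.data.frame(summaries))
    summaries <- do.call(rbind, lapply(summaries, gateSummaryTable))
  tot <- data.frame(tissue = "total",
                    n_stringent = sum(summaries$n_stringent),
                    n_enriched_cells = sum(summaries$n_enriched_cells),
                    proportion = if (sum(summaries$n_enriched_cells) > 0)
                      sum(summaries$n_stringent) / sum(summaries$n_enriched_cells)
                    else 0)
  writeTsv(rbind(summaries, tot), path,
           c("tissue", "n_stringent", "n_enriched_cells", "proportion"))
}

#' Write GSEA results as TSV
#'
#' Columns `set, size, es, nes, p_perm, fdr_q, significant`; rows sorted by
#' ascending `fdr_q`, ties by set name.
#'
#' @param results Data.frame from [prerankedGsea()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
writeGseaResults <- function(results, path) {
  df <- as.data.frame(results)
  df <- df[order(df$fdr_q, df$set), , drop = FALSE]
  writeTsv(df, path, c("set", "size", "es", "nes", "p_perm", "fdr_q",
                       "significant"))
}

#' Write a cross-tissue Venn partition as TSV
#'
#' Columns `pattern, n, genes`; rows sorted by decreasing pattern size then
#' pattern label.
#'
#' @param venn Data.frame from [crossTissueVenn()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
writeVennResult <- function(venn, path) {
  df <- as.data.frame(venn)
  df <- df[order(-df$n, df$pattern), , drop = FALSE]
  writeTsv(df, path, c("pattern", "n", "genes"))
}

#' Write simulation ground truth
#'
#' Cell-level truth as TSV (`barcode, tissue, cell_type, is_pericyte`) and
#' planted marker sets as JSON.
#'
#' @param sce A simulated `SingleCellExperiment` from
#'   [simulateTissueCounts()].
#' @param directory Output directory.
#' @return Invisibly, `directory`.
#' @export
writeGroundTruth <- function(sce, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  cd <- colData(sce)
  df <- data.frame(barcode = rownames(cd), tissue = cd$tissue,
                   cell_type = cd$cellType, is_pericyte = cd$isPericyte)
  writeTsv(df, file.path(directory, "ground_truth_cells.tsv"),
           c("barcode", "tissue", "cell_type", "is_pericyte"))
  truth <- metadata(sce)$truth
  jsonlite::write_json(
    truth[c("plantedMarkers", "sharedMarkers", "decoyMarkers")],
    file.path(directory, "ground_truth_markers.json"), pretty = TRUE)
  invisible(directory)
}
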