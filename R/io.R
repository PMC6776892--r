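## File I/O for the plain-text formats the pipeline consumes and emits.
## All files use BED-style 0-based half-open coordinates; in memory,
## intervals are GRanges (1-based closed). Conversion happens only here.

#' Read a chromosome-sizes file
#'
#' Two-column tab-separated file: chromosome name, length in bp.
#'
#' @param path File path.
#' @return Named integer vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  if (any(df$length <= 0)) stop("chromosome lengths must be > 0")
  if (anyDuplicated(df$chrom)) stop("duplicated chromosome names")
  stats::setNames(as.integer(df$length), df$chrom)
}

#' Write a chromosome-sizes file
#'
#' @param chromSizes Named integer vector.
#' @param path Output path.
#' @export
writeChromSizes <- function(chromSizes, path) {
  utils::write.table(data.frame(names(chromSizes), unname(chromSizes)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED3/BED6 file into a GRanges
#'
#' Accepts the 3- or 6-column BED dialect (tab-separated, 0-based
#' half-open). Track and comment lines are skipped. Records are validated;
#' malformed lines are reported with their line number. When
#' \code{chromSizes} is supplied, coordinates are checked against it and
#' the returned object carries seqlengths.
#'
#' @param path File path.
#' @param chromSizes Optional named vector of chromosome lengths.
#' @return \code{GRanges}; BED6 name/score/strand become mcols
#'   \code{name}, \code{score} and the strand.
#' @export
readBed <- function(path, chromSizes = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  lineNo <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    gr <- GRanges()
    if (!is.null(chromSizes))
      GenomeInfoDb::seqlevels(gr) <- names(chromSizes)
    return(gr)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    bad <- lineNo[which(nf < 3)[1]]
    stop(sprintf("%s line %d: fewer than 3 BED fields", path, bad))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  startChr <- vapply(fields, `[[`, "", 2L)
  endChr <- vapply(fields, `[[`, "", 3L)
  start0 <- suppressWarnings(as.numeric(startChr))
  end0 <- suppressWarnings(as.numeric(endChr))
  bad <- which(is.na(start0) | is.na(end0) |
               start0 != floor(start0) | end0 != floor(end0))
  if (length(bad))
    stop(sprintf("%s line %d: non-integer coordinates", path, lineNo[bad[1]]))
  bad <- which(start0 < 0 | start0 >= end0)
  if (length(bad))
    stop(sprintf("%s line %d: requires 0 <= start < end", path,
                 lineNo[bad[1]]))
  if (!is.null(chromSizes)) {
    bad <- which(!chrom %in% names(chromSizes))
    if (length(bad))
      stop(sprintf("%s line %d: unknown chromosome '%s'", path,
                   lineNo[bad[1]], chrom[bad[1]]))
    bad <- which(end0 > chromSizes[chrom])
    if (length(bad))
      stop(sprintf("%s line %d: interval exceeds chromosome length", path,
                   lineNo[bad[1]]))
  }
  gr <- GRanges(chrom, IRanges::IRanges(start = start0 + 1, end = end0))
  if (all(nf >= 6)) {
    mcols(gr)$name <- vapply(fields, `[[`, "", 4L)
    mcols(gr)$score <- suppressWarnings(
      as.numeric(vapply(fields, `[[`, "", 5L)))
    std <- vapply(fields, `[[`, "", 6L)
    std[!std %in% c("+", "-")] <- "*"
    strand(gr) <- std
  }
  if (!is.null(chromSizes)) {
    GenomeInfoDb::seqlevels(gr) <- names(chromSizes)
    seqlengths(gr) <- chromSizes
  }
  gr
}

#' Write a GRanges as BED
#'
#' Emits BED3, or BED6 when \code{bed6 = TRUE} (name/score taken from
#' mcols when present).
#'
#' @param gr \code{GRanges}.
#' @param path Output path.
#' @param bed6 Write six columns.
#' @export
writeBed <- function(gr, path, bed6 = FALSE) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr))
  if (bed6) {
    df$name <- if (!is.null(mcols(gr)$name)) mcols(gr)$name else
      paste0("feature_", seq_along(gr))
    df$score <- if (!is.null(mcols(gr)$score)) mcols(gr)$score else 0
    st <- as.character(strand(gr))
    st[st == "*"] <- "."
    df$strand <- st
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a PeakSet in a broadPeak-like dialect
#'
#' Columns: chrom, start, end, name, int(10 * score) capped at 1000,
#' strand (\code{.}), score, -log10 p, -log10 q.
#'
#' @param peaks A \linkS4class{PeakSet}.
#' @param path Output path.
#' @export
writePeaks <- function(peaks, path) {
  gr <- islands(peaks)
  df <- data.frame(
    chrom = as.character(seqnames(gr)),
    start = start(gr) - 1L, end = end(gr),
    name = sprintf("%s_%s_island_%d", cellState(peaks), chipMark(peaks),
                   seq_along(gr)),
    displayScore = pmin(as.integer(round(10 * mcols(gr)$score)), 1000L),
    strand = ".",
    score = mcols(gr)$score,
    negLog10P = -log10(pmax(mcols(gr)$pValue, .Machine$double.xmin)),
    negLog10Q = -log10(pmax(mcols(gr)$qValue, .Machine$double.xmin)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a broadPeak-like island file back into a PeakSet
#'
#' @param path File written by \code{\link{writePeaks}}.
#' @param cellState,chipMark Labels for the returned set.
#' @param chromSizes Optional chromosome lengths.
#' @return A \linkS4class{PeakSet} (fragmentCount is not stored in the
#'   dialect and is returned as \code{NA}).
#' @export
readPeaks <- function(path, cellState, chipMark, chromSizes = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE)
  gr <- GRanges(df[[1]], IRanges::IRanges(df[[2]] + 1, df[[3]]))
  mcols(gr)$fragmentCount <- NA_integer_
  mcols(gr)$score <- df[[7]]
  mcols(gr)$pValue <- 10^(-df[[8]])
  mcols(gr)$qValue <- 10^(-df[[9]])
  if (!is.null(chromSizes)) {
    GenomeInfoDb::seqlevels(gr) <- names(chromSizes)
    seqlengths(gr) <- chromSizes
  }
  PeakSet(gr, cellState, chipMark)
}

#' Read a gene annotation BED6
#'
#' BED6 where the name column holds the gene id and the strand locates the
#' TSS (interval start for \code{+}, interval end for \code{-}).
#'
#' @param path File path.
#' @param chromSizes Optional chromosome lengths.
#' @return \code{GRanges} with mcols \code{geneId}.
#' @export
readGeneAnnotation <- function(path, chromSizes = NULL) {
  gr <- readBed(path, chromSizes)
  if (is.null(mcols(gr)$name))
    stop("gene annotation must be BED6 with gene ids in the name column")
  mcols(gr)$geneId <- mcols(gr)$name
  mcols(gr)$name <- NULL
  mcols(gr)$score <- NULL
  if (anyDuplicated(mcols(gr)$geneId)) stop("gene ids must be unique")
  gr
}

#' Read a counts matrix with its sample sheet
#'
#' @param countsPath TSV of gene-level counts, first column gene ids,
#'   remaining columns one per sample.
#' @param sampleSheetPath TSV with columns \code{sample}, \code{state},
#'   \code{treatment}, \code{replicate}.
#' @return List with \code{counts} (integer matrix, rownames gene ids) and
#'   \code{sampleSheet} (data.frame).
#' @export
readCounts <- function(countsPath, sampleSheetPath) {
  df <- utils::read.table(countsPath, sep = "\t", header = TRUE,
                          check.names = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df[[1]]
  storage.mode(counts) <- "integer"
  ss <- utils::read.table(sampleSheetPath, sep = "\t", header = TRUE,
                          colClasses = "character")
  need <- c("sample", "state", "treatment", "replicate")
  if (!all(need %in% names(ss)))
    stop("sample sheet must have columns ",
         paste(need, collapse = ", "))
  if (!all(ss$treatment %in% c("vehicle", "EZH2i")))
    stop("treatment must be 'vehicle' or 'EZH2i'")
  if (!setequal(colnames(counts), ss$sample))
    stop("sample sheet does not match count matrix columns")
  counts <- counts[, ss$sample, drop = FALSE]
  list(counts = counts, sampleSheet = ss)
}

#' Write a counts matrix and sample sheet
#'
#' @param counts Integer matrix, rownames gene ids.
#' @param sampleSheet data.frame as in \code{\link{readCounts}}.
#' @param countsPath,sampleSheetPath Output paths.
#' @export
writeCounts <- function(counts, sampleSheet, countsPath, sampleSheetPath) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, countsPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sampleSheet, sampleSheetPath, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(countsPath)
}

#' Serialize a GroundTruthManifest to JSON
#'
#' The JSON round trip is lossless: \code{readManifest(writeManifest(x))}
#' reconstructs an identical manifest.
#'
#' @param manifest A \linkS4class{GroundTruthManifest}.
#' @param path Output path.
#' @export
writeManifest <- function(manifest, path) {
  dom <- plantedDomains(manifest)
  genes <- geneAnnotation(manifest)
  obj <- list(
    stateLabels = stateLabels(manifest),
    chromSizes = as.list(seqlengths(genes)),
    domains = data.frame(
      chrom = as.character(seqnames(dom)),
      start = start(dom) - 1L, end = end(dom),
      mark = dom$mark, states = dom$states,
      enrichment = dom$enrichment, domainId = dom$domainId),
    genes = data.frame(
      chrom = as.character(seqnames(genes)),
      start = start(genes) - 1L, end = end(genes),
      strand = as.character(strand(genes)), geneId = genes$geneId),
    sensitiveGenes = sensitiveGenes(manifest),
    switchGenes = switchGenes(manifest))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a GroundTruthManifest from JSON
#'
#' @param path File written by \code{\link{writeManifest}}.
#' @return A \linkS4class{GroundTruthManifest}.
#' @export
readManifest <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  chromSizes <- unlist(obj$chromSizes)
  si <- Seqinfo(names(chromSizes), seqlengths = chromSizes)
  dom <- if (NROW(obj$domains)) {
    d <- GRanges(obj$domains$chrom,
                 IRanges::IRanges(obj$domains$start + 1, obj$domains$end),
                 seqinfo = si)
    mcols(d)$mark <- obj$domains$mark
    mcols(d)$states <- obj$domains$states
    mcols(d)$enrichment <- as.numeric(obj$domains$enrichment)
    mcols(d)$domainId <- obj$domains$domainId
    d
  } else {
    d <- GRanges(seqinfo = si)
    mcols(d)$mark <- character()
    mcols(d)$states <- character()
    mcols(d)$enrichment <- numeric()
    mcols(d)$domainId <- character()
    d
  }
  genes <- GRanges(obj$genes$chrom,
                   IRanges::IRanges(obj$genes$start + 1, obj$genes$end),
                   strand = obj$genes$strand, seqinfo = si)
  mcols(genes)$geneId <- obj$genes$geneId
  sens <- lapply(obj$sensitiveGenes, as.character)
  sw <- if (NROW(obj$switchGenes)) as.data.frame(obj$switchGenes) else
    data.frame(geneId = character(), boundState = character(),
               expressionDirection = character())
  new("GroundTruthManifest", domains = dom, genes = genes,
      sensitiveGenes = sens, switchGenes = sw,
      stateLabels = obj$stateLabels)
}
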