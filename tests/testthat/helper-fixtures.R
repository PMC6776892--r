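## Small fixture builders shared across test files.

## FragmentSet from 0-based half-open triples (the BED convention used in
## examples), on a genome described by a named lengths vector.
fragmentSetFrom0 <- function(chrom, start0, end0, chromSizes,
                             state = "UT", mark = "EZH2", replicate = 1L) {
  si <- GenomeInfoDb::Seqinfo(names(chromSizes),
                              seqlengths = unname(chromSizes))
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start0 + 1, end0),
                               seqinfo = si)
  FragmentSet(gr, cellState = state, chipMark = mark,
              replicate = replicate)
}

## PeakSet from 0-based half-open intervals with default island stats.
peakSetFrom0 <- function(chrom, start0, end0, state = "UT",
                         mark = "EZH2", score = 10,
                         chromSizes = NULL) {
  gr <- if (is.null(chromSizes)) {
    GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0))
  } else {
    GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0),
      seqinfo = GenomeInfoDb::Seqinfo(names(chromSizes),
                                      seqlengths = unname(chromSizes)))
  }
  S4Vectors::mcols(gr)$fragmentCount <- rep(10L, length(gr))
  S4Vectors::mcols(gr)$score <- rep(score, length(gr))
  S4Vectors::mcols(gr)$pValue <- rep(1e-8, length(gr))
  S4Vectors::mcols(gr)$qValue <- rep(1e-6, length(gr))
  PeakSet(gr, state, mark)
}

## Window GRanges with prescribed counts, one chromosome, for callIslands.
windowFixture <- function(counts, windowSize = 200L) {
  n <- length(counts)
  si <- GenomeInfoDb::Seqinfo("chr1", seqlengths = n * windowSize)
  gr <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(seq(1, by = windowSize, length.out = n),
                     width = windowSize), seqinfo = si)
  S4Vectors::mcols(gr)$count <- as.integer(counts)
  gr
}

## librarySize that yields a prescribed background lambda in callIslands
## (with effectiveGenomeFraction 1 over the fixture genome).
libraryForLambda <- function(lambda, nWindows, windowSize = 200L) {
  lambda * nWindows
}

## Gene annotation GRanges from TSS positions (1-based), all on "+" so
## the TSS is the interval start.
genesAtTss <- function(tss1, chrom = "chr1", len = 500L,
                       ids = sprintf("g%02d", seq_along(tss1))) {
  gr <- GenomicRanges::GRanges(rep(chrom, length(tss1)),
                               IRanges::IRanges(tss1,
                                 width = rep(len, length(tss1))),
                               strand = rep("+", length(tss1)))
  S4Vectors::mcols(gr)$geneId <- ids
  gr
}

## Shared expensive simulations, computed once per test run.
.fixtureCache <- new.env(parent = emptyenv())

defaultStudy <- function() {
  if (is.null(.fixtureCache$default)) {
    .fixtureCache$default <- simulateStudy(simConfig(seed = 20260919L))
  }
  .fixtureCache$default
}

defaultPipeline <- function() {
  if (is.null(.fixtureCache$defaultRes)) {
    .fixtureCache$defaultRes <- suppressMessages(
      runPipeline(defaultStudy(), verbose = FALSE))
  }
  .fixtureCache$defaultRes
}

strongStudy <- function() {
  if (is.null(.fixtureCache$strong)) {
    .fixtureCache$strong <- simulateStudy(
      simConfig("strong", seed = 4130177L))
  }
  .fixtureCache$strong
}

strongPipeline <- function() {
  if (is.null(.fixtureCache$strongRes)) {
    .fixtureCache$strongRes <- suppressMessages(
      runPipeline(strongStudy(), verbose = FALSE))
  }
  .fixtureCache$strongRes
}

## Planted EZH2 domains carrying a given state.
plantedEzh2Domains <- function(manifest, state) {
  dom <- plantedDomains(manifest)
  keep <- dom$mark == "EZH2" &
    vapply(strsplit(dom$states, ",", fixed = TRUE),
           function(s) state %in% s, logical(1))
  dom[keep]
}
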