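## Broad-mark island calling: genome tiling into fixed windows, Poisson
## eligibility of windows against a uniform background, gap-tolerant
## clustering of eligible windows into islands, island-level Poisson
## significance with BH control, replicate consensus merging, and the
## H3K27me3 co-occupancy filter.

#' IslandParams: parameters of the broad-mark island caller
#'
#' @slot windowSizeBp Tiling window (default 200).
#' @slot gapSizeBp Maximum ineligible gap bridged inside an island
#'   (default 400 for EZH2, 600 for H3K27me3); must be a multiple of the
#'   window size.
#' @slot effectiveGenomeFraction Mappable fraction used for the background
#'   rate (default 0.75).
#' @slot redundancyThreshold Maximum identical fragments kept (default 1).
#' @slot eligibilityP Poisson tail probability below which a window counts
#'   as enriched-eligible (default 0.2).
#' @slot islandFdr BH threshold retaining islands (default 1e-4).
#' @slot fragmentSizeBp Single-end extension length; accepted for
#'   compatibility but unused when true fragment intervals are supplied.
#' @aliases IslandParams
#' @export
setClass("IslandParams",
  slots = c(windowSizeBp = "integer", gapSizeBp = "integer",
            effectiveGenomeFraction = "numeric",
            redundancyThreshold = "integer", eligibilityP = "numeric",
            islandFdr = "numeric", fragmentSizeBp = "integer"))

setValidity("IslandParams", function(object) {
  msg <- character()
  if (object@windowSizeBp <= 0) msg <- c(msg, "windowSizeBp must be > 0")
  if (object@gapSizeBp %% object@windowSizeBp != 0)
    msg <- c(msg, "gapSizeBp must be a multiple of windowSizeBp")
  if (object@effectiveGenomeFraction <= 0 ||
      object@effectiveGenomeFraction > 1)
    msg <- c(msg, "effectiveGenomeFraction must be in (0, 1]")
  if (object@islandFdr <= 0 || object@islandFdr >= 1)
    msg <- c(msg, "islandFdr must be in (0, 1)")
  if (object@eligibilityP <= 0 || object@eligibilityP >= 1)
    msg <- c(msg, "eligibilityP must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Construct island-calling parameters
#'
#' @param mark \code{"EZH2"} or \code{"H3K27me3"}; selects the default gap
#'   size (400 and 600 bp respectively).
#' @param windowSizeBp,gapSizeBp,effectiveGenomeFraction,
#'   redundancyThreshold,eligibilityP,islandFdr,fragmentSizeBp Overrides,
#'   see \linkS4class{IslandParams}.
#' @return An \linkS4class{IslandParams}.
#' @export
islandParams <- function(mark = c("EZH2", "H3K27me3"),
                         windowSizeBp = 200L,
                         gapSizeBp = NULL,
                         effectiveGenomeFraction = 0.75,
                         redundancyThreshold = 1L,
                         eligibilityP = 0.2,
                         islandFdr = 1e-4,
                         fragmentSizeBp = 110L) {
  mark <- match.arg(mark)
  if (is.null(gapSizeBp))
    gapSizeBp <- if (mark == "EZH2") 400L else 600L
  new("IslandParams", windowSizeBp = as.integer(windowSizeBp),
      gapSizeBp = as.integer(gapSizeBp),
      effectiveGenomeFraction = effectiveGenomeFraction,
      redundancyThreshold = as.integer(redundancyThreshold),
      eligibilityP = eligibilityP, islandFdr = islandFdr,
      fragmentSizeBp = as.integer(fragmentSizeBp))
}

#' Remove redundant identical fragments
#'
#' Retains at most \code{redundancyThreshold} fragments per identical
#' (chrom, start, end) triple, keeping the original order, and updates the
#' recorded library size.
#'
#' @param fragmentSet A \linkS4class{FragmentSet}.
#' @param redundancyThreshold Maximum copies kept (>= 1).
#' @return A deduplicated \linkS4class{FragmentSet}.
#' @export
deduplicateFragments <- function(fragmentSet, redundancyThreshold = 1L) {
  stopifnot(redundancyThreshold >= 1)
  gr <- fragments(fragmentSet)
  if (!length(gr)) return(fragmentSet)
  key <- paste(seqnames(gr), start(gr), end(gr))
  copy <- stats::ave(seq_along(key), key, FUN = seq_along)
  keep <- copy <= redundancyThreshold
  FragmentSet(gr[keep], cellState = fragmentSet@cellState,
              chipMark = fragmentSet@chipMark,
              replicate = fragmentSet@replicate,
              sampleId = fragmentSet@sampleId)
}

fragmentMidpoints <- function(gr) {
  ## BED-convention midpoint: floor((start0 + end0) / 2), expressed 1-based
  mid0 <- (start(gr) - 1 + end(gr)) %/% 2
  GRanges(seqnames(gr), IRanges::IRanges(mid0 + 1, width = 1L),
          seqinfo = seqinfo(gr))
}

#' Count fragments per genomic window
#'
#' Tiles every chromosome with disjoint fixed-size windows and assigns
#' each fragment to exactly one window by its midpoint, so the window
#' counts conserve the library size.
#'
#' @param fragmentSet A (deduplicated) \linkS4class{FragmentSet}.
#' @param chromSizes Named integer vector of chromosome lengths.
#' @param windowSizeBp Window width in bp.
#' @return \code{GRanges} of all windows with an integer mcol
#'   \code{count} (the last window of a chromosome may be short).
#' @export
windowCounts <- function(fragmentSet, chromSizes, windowSizeBp = 200L) {
  gr <- fragments(fragmentSet)
  if (length(gr)) {
    if (any(!as.character(seqnames(gr)) %in% names(chromSizes)) ||
        any(end(gr) > chromSizes[as.character(seqnames(gr))]) ||
        any(start(gr) < 1))
      stop("fragments outside chromosome bounds")
  }
  tiles <- tileGenome(chromSizes, tilewidth = windowSizeBp,
                      cut.last.tile.in.chrom = TRUE)
  mcols(tiles)$count <- countOverlaps(tiles, fragmentMidpoints(gr))
  tiles
}

#' Call broad enriched islands from window counts
#'
#' The background per-window mean is
#' \eqn{\lambda = librarySize \cdot windowSize / (genomeLength \cdot
#' effectiveGenomeFraction)}. A window is eligible iff its count reaches
#' the smallest integer whose Poisson upper-tail probability is at most
#' \code{eligibilityP}. Islands are maximal runs of eligible windows in
#' which consecutive eligible windows are separated by at most
#' \code{gapSizeBp} of ineligible windows. The island score sums
#' \eqn{-\ln P(X \ge count | \lambda)} over its eligible windows; the
#' island p-value is the Poisson upper tail of its total fragment count at
#' mean \eqn{\lambda \times} (windows spanned); q-values are
#' Benjamini-Hochberg across candidate islands and islands with
#' \code{qValue < islandFdr} are retained.
#'
#' @param windows Output of \code{\link{windowCounts}}.
#' @param params An \linkS4class{IslandParams}.
#' @param librarySize Fragment count of the sample.
#' @param genomeLengthBp Total genome length.
#' @param cellState,chipMark,provenance Labels for the returned set.
#' @return A \linkS4class{PeakSet}.
#' @export
callIslands <- function(windows, params, librarySize, genomeLengthBp,
                        cellState = "NA", chipMark = "EZH2",
                        provenance = character()) {
  validObject(params)
  w <- params@windowSizeBp
  emptyPeaks <- function() {
    gr <- GRanges(seqinfo = seqinfo(windows))
    mcols(gr)$fragmentCount <- integer()
    mcols(gr)$score <- numeric()
    mcols(gr)$pValue <- numeric()
    mcols(gr)$qValue <- numeric()
    PeakSet(gr, cellState, chipMark, provenance)
  }
  lambda <- librarySize * w /
    (genomeLengthBp * params@effectiveGenomeFraction)
  if (lambda == 0) {
    warning("empty library: no islands can be called")
    return(emptyPeaks())
  }
  c0 <- eligibilityThreshold(lambda, params@eligibilityP)
  gapWindows <- params@gapSizeBp %/% w

  counts <- mcols(windows)$count
  chrom <- as.character(seqnames(windows))
  cand <- list()
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    cnt <- counts[idx]
    elig <- which(cnt >= c0)
    if (!length(elig)) next
    ## break runs where more than gapWindows ineligible windows intervene
    newRun <- c(TRUE, diff(elig) - 1L > gapWindows)
    runId <- cumsum(newRun)
    for (r in unique(runId)) {
      e <- elig[runId == r]
      first <- e[1]; last <- e[length(e)]
      span <- idx[first:last]
      total <- sum(counts[span])
      score <- sum(-poissonLogUpperTail(cnt[e], lambda))
      logp <- poissonLogUpperTail(total, lambda * length(span))
      cand[[length(cand) + 1L]] <- data.frame(
        chrom = ch,
        start = start(windows)[idx[first]],
        end = end(windows)[idx[last]],
        fragmentCount = total, score = score, logP = logp)
    }
  }
  if (!length(cand)) return(emptyPeaks())
  df <- do.call(rbind, cand)
  df$pValue <- exp(df$logP)
  df$qValue <- bhAdjust(df$pValue)
  df <- df[df$qValue < params@islandFdr, , drop = FALSE]
  if (!nrow(df)) return(emptyPeaks())
  gr <- GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                seqinfo = seqinfo(windows))
  mcols(gr)$fragmentCount <- as.integer(df$fragmentCount)
  mcols(gr)$score <- df$score
  mcols(gr)$pValue <- df$pValue
  mcols(gr)$qValue <- df$qValue
  PeakSet(gr, cellState, chipMark, provenance)
}

#' Call islands for one sample end to end
#'
#' Deduplication, window counting and island calling in one step.
#'
#' @param fragmentSet A \linkS4class{FragmentSet}.
#' @param chromSizes Named chromosome lengths.
#' @param params An \linkS4class{IslandParams}; defaults to the mark's
#'   standard parameters.
#' @return A \linkS4class{PeakSet}.
#' @export
callSampleIslands <- function(fragmentSet, chromSizes, params = NULL) {
  if (is.null(params)) params <- islandParams(fragmentSet@chipMark)
  dedup <- deduplicateFragments(fragmentSet, params@redundancyThreshold)
  wins <- windowCounts(dedup, chromSizes, params@windowSizeBp)
  callIslands(wins, params, librarySize(dedup),
              sum(as.numeric(chromSizes)),
              cellState = dedup@cellState, chipMark = dedup@chipMark,
              provenance = dedup@sampleId)
}

#' Merge replicate peak sets into a per-state consensus
#'
#' Takes the union of the replicates' islands, merges overlapping
#' intervals, and additionally merges any two resulting intervals
#' separated by strictly less than \code{mergeGapBp}. Fragment counts are
#' summed and the score of a merged island is the maximum constituent
#' score; p- and q-values are the constituent minima.
#'
#' @param peakSets List of \linkS4class{PeakSet} for the same state and
#'   mark.
#' @param mergeGapBp Gap below which intervals are merged (strictly less
#'   than; default 250).
#' @return A consensus \linkS4class{PeakSet}.
#' @export
mergeReplicates <- function(peakSets, mergeGapBp = 250L) {
  stopifnot(length(peakSets) >= 1)
  st <- unique(vapply(peakSets, cellState, ""))
  mk <- unique(vapply(peakSets, chipMark, ""))
  if (length(st) != 1 || length(mk) != 1)
    stop("all replicates must share state and mark")
  all <- do.call(c, unname(lapply(peakSets, islands)))
  if (!length(all)) {
    return(PeakSet(all, st, mk,
                   unlist(lapply(peakSets, function(p) p@provenance))))
  }
  ## min.gapwidth = g merges gaps <= g - 1, i.e. strictly less than g
  merged <- reduce(all, min.gapwidth = mergeGapBp)
  hit <- findOverlaps(all, merged)
  grp <- subjectHits(hit)
  mcols(merged)$fragmentCount <- as.integer(
    rowsum(as.numeric(all$fragmentCount[queryHits(hit)]), grp))
  mcols(merged)$score <- unname(vapply(
    split(all$score[queryHits(hit)], grp), max, 0))
  mcols(merged)$pValue <- unname(vapply(
    split(all$pValue[queryHits(hit)], grp), min, 0))
  mcols(merged)$qValue <- unname(vapply(
    split(all$qValue[queryHits(hit)], grp), min, 0))
  PeakSet(merged, st, mk,
          unlist(lapply(peakSets, function(p) p@provenance)))
}

#' Retain EZH2 islands co-occupied by H3K27me3
#'
#' An EZH2 island is kept iff the total overlap with the union of
#' H3K27me3 islands exceeds \code{minFraction} of the island's width
#' (strictly greater).
#'
#' @param ezh2 EZH2 \linkS4class{PeakSet}.
#' @param k27 H3K27me3 \linkS4class{PeakSet} for the same state.
#' @param minFraction Minimum overlap fraction (default 0.25, strict).
#' @return Filtered EZH2 \linkS4class{PeakSet}.
#' @export
filterCooccupancy <- function(ezh2, k27, minFraction = 0.25) {
  if (cellState(ezh2) != cellState(k27))
    stop("co-occupancy filter requires matching states")
  ez <- islands(ezh2)
  if (!length(ez)) return(ezh2)
  k27u <- reduce(islands(k27))
  hit <- findOverlaps(ez, k27u)
  ovw <- width(pintersect(ez[queryHits(hit)], k27u[subjectHits(hit)]))
  perIsland <- rep(0, length(ez))
  if (length(hit)) {
    agg <- rowsum(as.numeric(ovw), queryHits(hit))
    perIsland[as.integer(rownames(agg))] <- agg[, 1]
  }
  keep <- perIsland > minFraction * width(ez)
  PeakSet(ez[keep], cellState(ezh2), chipMark(ezh2), ezh2@provenance)
}

#' Recall and precision of islands against planted domains
#'
#' A planted domain counts as recovered when some island achieves
#' reciprocal overlap of at least \code{minReciprocal} with it; an island
#' counts as a true call under the same rule.
#'
#' @param peaks A \linkS4class{PeakSet} (or \code{GRanges}).
#' @param domains \code{GRanges} of planted domains.
#' @param minReciprocal Reciprocal-overlap threshold (default 0.5).
#' @return Named numeric vector \code{recall}, \code{precision}.
#' @export
domainRecovery <- function(peaks, domains, minReciprocal = 0.5) {
  gr <- if (is(peaks, "PeakSet")) islands(peaks) else peaks
  if (!length(domains))
    return(c(recall = NA_real_,
             precision = if (length(gr)) 0 else NA_real_))
  if (!length(gr)) return(c(recall = 0, precision = NA_real_))
  hit <- findOverlaps(gr, domains)
  ovw <- width(pintersect(gr[queryHits(hit)], domains[subjectHits(hit)]))
  good <- ovw >= minReciprocal * width(gr)[queryHits(hit)] &
    ovw >= minReciprocal * width(domains)[subjectHits(hit)]
  c(recall = length(unique(subjectHits(hit)[good])) / length(domains),
    precision = length(unique(queryHits(hit)[good])) / length(gr))
}
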