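## Differential-binding module: union of two states' consensus islands,
## normalized tag counts over pooled replicates, a bidirectional Poisson
## enrichment test, and the large-magnitude classification
## (fold change >= 1.5, p <= 1e-20, both inclusive).

#' DiffParams: thresholds of the differential-binding test
#'
#' @slot fcMin Minimum fold change (inclusive, default 1.5).
#' @slot pMax Maximum Poisson p-value (inclusive, default 1e-20).
#' @slot normDepth Tags-per-N normalization depth (default 1e7).
#' @slot pseudocount Added to normalized counts in the fold change and
#'   used as the minimum Poisson mean (default 1).
#' @slot displayPFloor Volcano-display floor for p-values (default
#'   1e-100); classification always uses the unfloored value.
#' @aliases DiffParams
#' @export
setClass("DiffParams",
  slots = c(fcMin = "numeric", pMax = "numeric", normDepth = "numeric",
            pseudocount = "numeric", displayPFloor = "numeric"))

setValidity("DiffParams", function(object) {
  msg <- character()
  if (object@fcMin < 1) msg <- c(msg, "fcMin must be >= 1")
  if (object@pMax <= 0 || object@pMax >= 1)
    msg <- c(msg, "pMax must be in (0, 1)")
  if (object@pseudocount <= 0) msg <- c(msg, "pseudocount must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct differential-binding parameters
#'
#' @param fcMin,pMax,normDepth,pseudocount,displayPFloor See
#'   \linkS4class{DiffParams}.
#' @return A \linkS4class{DiffParams}.
#' @export
diffParams <- function(fcMin = 1.5, pMax = 1e-20, normDepth = 1e7,
                       pseudocount = 1, displayPFloor = 1e-100) {
  new("DiffParams", fcMin = fcMin, pMax = pMax, normDepth = normDepth,
      pseudocount = pseudocount, displayPFloor = displayPFloor)
}

#' Union binding sites of two states
#'
#' Islands of the two consensus sets that overlap by at least 1 bp are
#' fused into a single \code{common} interval spanning both;
#' non-overlapping islands keep their extent with origin \code{A-only} or
#' \code{B-only}. Bookended (zero-overlap) islands are not fused.
#'
#' @param peaksA,peaksB Co-occupancy-filtered consensus
#'   \linkS4class{PeakSet}s of states A and B.
#' @return \code{GRanges} of sorted, non-overlapping sites with mcols
#'   \code{siteId} and \code{origin}.
#' @export
siteUnion <- function(peaksA, peaksB) {
  grA <- granges(islands(peaksA))
  grB <- granges(islands(peaksB))
  ## min.gapwidth = 0 merges only truly overlapping ranges
  u <- reduce(c(grA, grB), min.gapwidth = 0L)
  inA <- countOverlaps(u, grA, minoverlap = 1L) > 0
  inB <- countOverlaps(u, grB, minoverlap = 1L) > 0
  mcols(u)$origin <- ifelse(inA & inB, "common",
                            ifelse(inA, "A-only", "B-only"))
  mcols(u)$siteId <- sprintf("site_%04d", seq_along(u))
  u
}

#' Normalized tag count over an interval set
#'
#' Counts pooled fragment midpoints inside each interval and scales to
#' tags per \code{normDepth} library fragments.
#'
#' @param fragmentSets List of \linkS4class{FragmentSet} replicates for
#'   one state and mark (pooled).
#' @param sites \code{GRanges} of intervals.
#' @param normDepth Normalization depth (default 1e7).
#' @return Numeric vector of normalized counts, one per site.
#' @export
normalizedCount <- function(fragmentSets, sites, normDepth = 1e7) {
  if (is(fragmentSets, "FragmentSet")) fragmentSets <- list(fragmentSets)
  pooled <- do.call(c, unname(lapply(fragmentSets, function(fs)
    granges(fragments(fs)))))
  pooledLibrary <- sum(vapply(fragmentSets, librarySize, 0L))
  if (pooledLibrary == 0) stop("pooled library size is zero")
  raw <- countOverlaps(sites, fragmentMidpoints(pooled))
  raw * normDepth / pooledLibrary
}

#' Poisson differential-enrichment test for one direction
#'
#' \code{foldChange = (target + pseudocount) / (background +
#' pseudocount)}; \code{pValue} is the Poisson upper tail of
#' \code{round(target)} at mean \code{max(background, pseudocount)},
#' computed in log space.
#'
#' @param target,background Normalized tag counts (>= 0), vectorized.
#' @param params A \linkS4class{DiffParams}.
#' @return \code{data.frame} with \code{foldChange}, \code{pValue} and
#'   \code{logP} (natural log, exact far below double underflow).
#' @export
poissonDiffTest <- function(target, background, params = diffParams()) {
  if (any(target < 0) || any(background < 0))
    stop("counts must be non-negative")
  pc <- params@pseudocount
  fold <- (target + pc) / (background + pc)
  logp <- poissonLogUpperTail(round(target), pmax(background, pc))
  data.frame(foldChange = fold, pValue = exp(logp), logP = logp)
}

#' Classify union sites as state-enriched or unchanged
#'
#' Runs the Poisson test in both directions around the site union.
#' A site is \code{A-enriched} iff fold(A over B) >= \code{fcMin} and
#' p(A over B) <= \code{pMax} (both inclusive); symmetric for B; all other
#' sites are \code{unchanged}. In the degenerate case where both
#' directions qualify the site is set to \code{unchanged}. Also returns a
#' volcano table with the display p floored at \code{displayPFloor}
#' (classification uses the unfloored value).
#'
#' @param sites Output of \code{\link{siteUnion}}.
#' @param fragmentsA,fragmentsB Lists of \linkS4class{FragmentSet}
#'   replicates for the two states (same mark).
#' @param params A \linkS4class{DiffParams}.
#' @return List with \code{sites} (the input \code{GRanges} with mcols
#'   \code{normCountA}, \code{normCountB}, \code{foldAoverB},
#'   \code{foldBoverA}, \code{logPA}, \code{logPB}, \code{class}) and
#'   \code{volcano} (\code{data.frame} of signed log2 fold and capped
#'   -log10 p).
#' @export
classifySites <- function(sites, fragmentsA, fragmentsB,
                          params = diffParams()) {
  nA <- normalizedCount(fragmentsA, sites, params@normDepth)
  nB <- normalizedCount(fragmentsB, sites, params@normDepth)
  classifyFromCounts(sites, nA, nB, params)
}

#' Classify union sites from precomputed normalized counts
#'
#' @param sites \code{GRanges} of union sites.
#' @param normCountA,normCountB Normalized tag counts per site.
#' @param params A \linkS4class{DiffParams}.
#' @return As \code{\link{classifySites}}.
#' @export
classifyFromCounts <- function(sites, normCountA, normCountB,
                               params = diffParams()) {
  testA <- poissonDiffTest(normCountA, normCountB, params)  # A over B
  testB <- poissonDiffTest(normCountB, normCountA, params)  # B over A
  logPmax <- log(params@pMax)
  passA <- testA$foldChange >= params@fcMin & testA$logP <= logPmax
  passB <- testB$foldChange >= params@fcMin & testB$logP <= logPmax
  class <- rep("unchanged", length(sites))
  class[passA & !passB] <- "A-enriched"
  class[passB & !passA] <- "B-enriched"
  mcols(sites)$normCountA <- normCountA
  mcols(sites)$normCountB <- normCountB
  mcols(sites)$foldAoverB <- testA$foldChange
  mcols(sites)$foldBoverA <- testB$foldChange
  mcols(sites)$logPA <- testA$logP
  mcols(sites)$logPB <- testB$logP
  mcols(sites)$class <- class

  ## volcano: signed toward B, display p floored
  signedLog2 <- log2(testB$foldChange)
  dirLogP <- ifelse(signedLog2 >= 0, testB$logP, testA$logP)
  negLog10P <- pmin(-dirLogP / log(10), -log10(params@displayPFloor))
  volcano <- data.frame(siteId = mcols(sites)$siteId,
                        log2FoldChange = signedLog2,
                        negLog10P = negLog10P,
                        class = class, stringsAsFactors = FALSE)
  list(sites = sites, volcano = volcano)
}

#' Validate differential sites against an extra replicate
#'
#' Fraction of A-enriched and B-enriched sites overlapping (>= 1 bp) the
#' islands of an independent replicate.
#'
#' @param sites Classified sites (\code{GRanges} with \code{class}).
#' @param extraReplicate A \linkS4class{PeakSet} from the extra replicate.
#' @return \code{data.frame} with per-class \code{n}, \code{validated} and
#'   \code{fraction}.
#' @export
replicateValidation <- function(sites, extraReplicate) {
  extra <- islands(extraReplicate)
  out <- lapply(c("A-enriched", "B-enriched"), function(cl) {
    s <- sites[mcols(sites)$class == cl]
    hit <- if (length(s)) countOverlaps(s, extra, minoverlap = 1L) > 0
      else logical()
    data.frame(class = cl, n = length(s), validated = sum(hit),
               fraction = if (length(s)) mean(hit) else 0)
  })
  do.call(rbind, out)
}
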