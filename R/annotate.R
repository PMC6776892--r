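## Annotation module: site-to-TSS assignment with the equidistance tie
## rule and the 5 kb promoter window, feature-track overlap tables, and
## the exact tests (two-tailed Fisher, hypergeometric gene-set overlap).

geneTssPositions <- function(genes) {
  ifelse(as.character(strand(genes)) == "+", start(genes), end(genes))
}

#' Annotate sites to genes by TSS proximity
#'
#' A site's distance to a TSS is 0 when the TSS lies inside the site,
#' otherwise the distance to the nearer site edge. Each site is assigned
#' ALL genes whose TSS falls inside it; if none does, all genes achieving
#' the minimum positive distance (exact-bp equidistance ties are all
#' kept). Assignments farther than \code{maxDistBp} are discarded.
#'
#' @param sites \code{GRanges} of sites (mcol \code{siteId} used if
#'   present).
#' @param genes \code{GRanges} gene annotation with mcols \code{geneId};
#'   strand determines the TSS (start for \code{+}, end for \code{-}).
#' @param maxDistBp Maximum TSS distance (default 5000, inclusive).
#' @return \code{data.frame} with \code{siteId}, \code{geneId},
#'   \code{distance}; zero rows when nothing qualifies.
#' @export
annotateSites <- function(sites, genes, maxDistBp = 5000L) {
  empty <- data.frame(siteId = character(), geneId = character(),
                      distance = integer(), stringsAsFactors = FALSE)
  if (!length(sites)) return(empty)
  if (!length(genes)) {
    warning("empty gene annotation")
    return(empty)
  }
  siteId <- if (!is.null(mcols(sites)$siteId)) mcols(sites)$siteId else
    sprintf("site_%04d", seq_along(sites))
  tssPos <- geneTssPositions(genes)
  tss <- GRanges(seqnames(genes), IRanges::IRanges(tssPos, width = 1L))
  win <- suppressWarnings(
    resize(granges(sites), width(sites) + 2 * maxDistBp, fix = "center"))
  win <- GenomicRanges::trim(win)
  hit <- findOverlaps(win, tss, ignore.strand = TRUE)
  if (!length(hit)) return(empty)
  si <- queryHits(hit); gi <- subjectHits(hit)
  pos <- tssPos[gi]
  s <- start(sites)[si]; e <- end(sites)[si]
  inside <- pos >= s & pos <= e
  dist <- ifelse(inside, 0L, pmin(abs(pos - s), abs(pos - e)))
  keep <- dist <= maxDistBp
  df <- data.frame(site = si, geneId = genes$geneId[gi],
                   distance = as.integer(dist))[keep, , drop = FALSE]
  if (!nrow(df)) return(empty)
  ## per site: all TSSs inside, else all at the minimum positive distance
  res <- do.call(rbind, lapply(split(df, df$site), function(d) {
    if (any(d$distance == 0)) d[d$distance == 0, , drop = FALSE]
    else d[d$distance == min(d$distance), , drop = FALSE]
  }))
  data.frame(siteId = siteId[res$site], geneId = res$geneId,
             distance = res$distance, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Feature-track overlap counts per site class
#'
#' A site overlaps the track iff the intersection is at least 1 bp; the
#' two counts partition each class.
#'
#' @param sites Classified sites (\code{GRanges} with mcol \code{class}).
#' @param track \code{GRanges} feature track (internally merged).
#' @param classes Classes to tabulate (default common / A-enriched /
#'   B-enriched).
#' @return \code{data.frame} with \code{class}, \code{overlapping},
#'   \code{nonOverlapping}.
#' @export
featureOverlapTable <- function(sites, track,
                                classes = c("common", "A-enriched",
                                            "B-enriched")) {
  trk <- reduce(granges(track))
  cls <- mcols(sites)$class
  if (is.null(cls)) cls <- mcols(sites)$origin
  out <- lapply(classes, function(cl) {
    s <- sites[cls == cl]
    ov <- if (length(s)) countOverlaps(s, trk, minoverlap = 1L) > 0
      else logical()
    data.frame(class = cl, overlapping = sum(ov),
               nonOverlapping = sum(!ov))
  })
  do.call(rbind, out)
}

#' Two-tailed Fisher's exact test for a 2x2 table
#'
#' Conditional hypergeometric test; the two-tailed p-value follows the
#' point-probability rule (the sum over all tables with the observed
#' margins whose probability does not exceed the observed table's, within
#' a 1e-7 relative tolerance for floating-point ties). The odds ratio is
#' the simple cross-product ratio.
#'
#' @param tab 2x2 matrix (or length-4 vector, row-wise a, b, c, d) of
#'   non-negative integer counts.
#' @return List with \code{oddsRatio} (NaN when 0/0) and \code{pValue}.
#' @export
fisherExactTwoTailed <- function(tab) {
  x <- as.vector(t(as.matrix(tab)))
  if (length(x) != 4) stop("need a 2x2 table")
  if (any(x < 0)) stop("counts must be non-negative")
  a <- x[1]; b <- x[2]; cc <- x[3]; d <- x[4]
  m <- a + b          # row 1 total
  n <- cc + d         # row 2 total
  k <- a + cc         # column 1 total
  orat <- (a * d) / (b * cc)
  if (k == 0 || m + n == k || m == 0 || n == 0)
    return(list(oddsRatio = orat, pValue = 1))
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  pObs <- stats::dhyper(a, m, n, k)
  p <- sum(probs[probs <= pObs * (1 + 1e-7)])
  list(oddsRatio = orat, pValue = min(p, 1))
}

#' Upper-tail hypergeometric gene-set overlap test
#'
#' Probability of observing at least the given overlap between a hit list
#' and a gene set drawn from a common universe.
#'
#' @param hits Character vector of hit genes (must lie in
#'   \code{universe}).
#' @param geneSet Character vector, the signature gene set.
#' @param universe Character vector of all testable genes.
#' @return List with \code{overlap}, \code{expected} and \code{pValue}.
#' @export
genesetOverlapTest <- function(hits, geneSet, universe) {
  hits <- unique(hits); geneSet <- unique(geneSet)
  universe <- unique(universe)
  if (!all(hits %in% universe))
    stop("hits must be a subset of the universe")
  geneSet <- intersect(geneSet, universe)
  ov <- length(intersect(hits, geneSet))
  N <- length(universe)
  p <- stats::phyper(ov - 1, length(geneSet), N - length(geneSet),
                     length(hits), lower.tail = FALSE)
  list(overlap = ov,
       expected = length(hits) * length(geneSet) / N,
       pValue = p)
}

#' Feature enrichment of differential versus common sites
#'
#' For each differential class, a two-tailed Fisher test of
#' (overlapping, non-overlapping) counts against the common class.
#'
#' @param overlapTable Output of \code{\link{featureOverlapTable}}.
#' @param reference Class used as the comparison baseline
#'   (default \code{"common"}).
#' @return \code{data.frame} with per-class counts, odds ratio and
#'   p-value.
#' @export
featureEnrichment <- function(overlapTable, reference = "common") {
  ref <- overlapTable[overlapTable$class == reference, ]
  if (!nrow(ref)) stop("reference class not present")
  rows <- overlapTable[overlapTable$class != reference, ]
  out <- lapply(seq_len(nrow(rows)), function(i) {
    ft <- fisherExactTwoTailed(matrix(c(rows$overlapping[i],
                                        rows$nonOverlapping[i],
                                        ref$overlapping,
                                        ref$nonOverlapping),
                                      nrow = 2, byrow = TRUE))
    data.frame(class = rows$class[i], overlapping = rows$overlapping[i],
               nonOverlapping = rows$nonOverlapping[i],
               oddsRatio = ft$oddsRatio, pValue = ft$pValue)
  })
  do.call(rbind, out)
}
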