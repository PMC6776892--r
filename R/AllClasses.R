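#' @import methods
#' @importFrom GenomicRanges GRanges
NULL

#' FragmentSet: one sample's ChIP fragment intervals
#'
#' A light S4 wrapper around a \link[GenomicRanges]{GRanges} of sequenced
#' chromatin fragments for a single immunoprecipitation sample, carrying the
#' sample's cellular state, the profiled mark, the replicate index and the
#' library size. Coordinates follow the usual Bioconductor 1-based closed
#' convention internally; BED input/output converts at the boundary.
#'
#' @slot fragments \code{GRanges} of fragment intervals with seqlengths set.
#' @slot sampleId Character scalar identifying the sample.
#' @slot cellState Character scalar, e.g. \code{"UT"} or \code{"TR"}.
#' @slot chipMark Character scalar, e.g. \code{"EZH2"} or \code{"H3K27me3"}.
#' @slot replicate Integer replicate index (1-based).
#' @slot librarySize Integer; must equal the number of fragments.
#' @aliases FragmentSet
#' @export
setClass("FragmentSet",
  slots = c(
    fragments   = "GRanges",
    sampleId    = "character",
    cellState   = "character",
    chipMark    = "character",
    replicate   = "integer",
    librarySize = "integer"
  )
)

setValidity("FragmentSet", function(object) {
  msg <- character()
  if (object@librarySize != length(object@fragments))
    msg <- c(msg, "librarySize must equal the number of fragments")
  sl <- GenomeInfoDb::seqlengths(object@fragments)
  if (length(object@fragments)) {
    if (any(is.na(sl)))
      msg <- c(msg, "fragment seqlengths must be set")
    else if (any(GenomicRanges::end(object@fragments) >
                 sl[as.character(GenomeInfoDb::seqnames(object@fragments))]))
      msg <- c(msg, "fragments extend beyond chromosome bounds")
    if (any(GenomicRanges::width(object@fragments) < 1))
      msg <- c(msg, "fragments must have width >= 1")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a FragmentSet
#'
#' @param fragments \code{GRanges} of fragments (seqlengths must be set).
#' @param sampleId Sample identifier; defaults to
#'   \code{"<state>_<mark>_rep<replicate>"}.
#' @param cellState,chipMark,replicate Sample metadata.
#' @return A \linkS4class{FragmentSet}.
#' @export
FragmentSet <- function(fragments, cellState, chipMark, replicate = 1L,
                        sampleId = sprintf("%s_%s_rep%d", cellState,
                                           chipMark, replicate)) {
  new("FragmentSet", fragments = fragments, sampleId = sampleId,
      cellState = as.character(cellState), chipMark = as.character(chipMark),
      replicate = as.integer(replicate),
      librarySize = length(fragments))
}

#' PeakSet: called or merged broad-mark islands
#'
#' Islands for one cellular state and mark: a sorted, non-overlapping
#' \code{GRanges} with per-island metadata columns \code{fragmentCount},
#' \code{score} (sum over eligible windows of minus-log Poisson tails),
#' \code{pValue} and \code{qValue}, plus the provenance of contributing
#' replicate samples.
#'
#' @slot islands \code{GRanges}, sorted, non-overlapping.
#' @slot cellState,chipMark Character scalars.
#' @slot provenance Character vector of contributing sample ids.
#' @aliases PeakSet
#' @export
setClass("PeakSet",
  slots = c(
    islands    = "GRanges",
    cellState  = "character",
    chipMark   = "character",
    provenance = "character"
  )
)

setValidity("PeakSet", function(object) {
  msg <- character()
  gr <- object@islands
  need <- c("fragmentCount", "score", "pValue", "qValue")
  if (!all(need %in% names(S4Vectors::mcols(gr))))
    msg <- c(msg, paste("islands must carry mcols",
                        paste(need, collapse = ", ")))
  if (length(gr) > 1) {
    if (S4Vectors::isSorted(gr) == FALSE)
      msg <- c(msg, "islands must be sorted")
    if (!isDisjoint(gr))
      msg <- c(msg, "islands must be non-overlapping")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PeakSet
#'
#' @param islands \code{GRanges} with mcols \code{fragmentCount},
#'   \code{score}, \code{pValue}, \code{qValue}.
#' @param cellState,chipMark Metadata labels.
#' @param provenance Sample ids the islands derive from.
#' @return A \linkS4class{PeakSet}.
#' @export
PeakSet <- function(islands, cellState, chipMark, provenance = character()) {
  islands <- GenomicRanges::sort(islands)
  new("PeakSet", islands = islands, cellState = as.character(cellState),
      chipMark = as.character(chipMark), provenance = provenance)
}

#' GroundTruthManifest: planted truth for a synthetic study
#'
#' Machine-readable record of everything the synthetic-data generator
#' planted: enriched domains (with mark, carrying states and enrichment),
#' the gene annotation, per-state inhibitor-sensitive gene sets, and the
#' switch genes whose promoter binding is gained in exactly one state with
#' a concordant between-state expression change. It is the oracle against
#' which parameter-recovery tests compare pipeline output.
#'
#' @slot domains \code{GRanges} with mcols \code{mark}, \code{states}
#'   (comma-separated labels), \code{enrichment}, \code{domainId}.
#' @slot genes \code{GRanges} of gene bodies with mcols \code{geneId} and
#'   strand set; the TSS is the start for \code{+} genes and the end for
#'   \code{-} genes.
#' @slot sensitiveGenes Named list: state -> character vector of gene ids
#'   with a planted inhibitor response.
#' @slot switchGenes \code{data.frame} with columns \code{geneId},
#'   \code{boundState} (state where promoter binding is present/gained) and
#'   \code{expressionDirection} (\code{"down"} in the bound state).
#' @slot stateLabels Character vector of state labels, reference first.
#' @aliases GroundTruthManifest
#' @export
setClass("GroundTruthManifest",
  slots = c(
    domains        = "GRanges",
    genes          = "GRanges",
    sensitiveGenes = "list",
    switchGenes    = "data.frame",
    stateLabels    = "character"
  )
)

setValidity("GroundTruthManifest", function(object) {
  msg <- character()
  sl <- GenomeInfoDb::seqlengths(object@domains)
  if (length(object@domains) && any(is.na(sl)))
    msg <- c(msg, "domain seqlengths must be set")
  if (length(object@domains) &&
      any(GenomicRanges::end(object@domains) >
          sl[as.character(GenomeInfoDb::seqnames(object@domains))]))
    msg <- c(msg, "domains extend beyond chromosome bounds")
  if (!all(c("geneId") %in% names(S4Vectors::mcols(object@genes))))
    msg <- c(msg, "genes must carry a geneId column")
  if (anyDuplicated(object@genes$geneId))
    msg <- c(msg, "gene ids must be unique")
  if (nrow(object@switchGenes) &&
      !all(object@switchGenes$geneId %in% object@genes$geneId))
    msg <- c(msg, "switch genes must be present in the annotation")
  if (!all(names(object@sensitiveGenes) %in% object@stateLabels))
    msg <- c(msg, "sensitive-gene states must be among stateLabels")
  if (length(msg)) msg else TRUE
})

## ---- accessors ----

#' @rdname FragmentSet-class
#' @param object,x A FragmentSet, PeakSet or GroundTruthManifest.
#' @export
setGeneric("fragments", function(x) standardGeneric("fragments"))
#' @rdname FragmentSet-class
#' @export
setMethod("fragments", "FragmentSet", function(x) x@fragments)

#' @rdname PeakSet-class
#' @export
setGeneric("islands", function(x) standardGeneric("islands"))
#' @rdname PeakSet-class
#' @param x A PeakSet.
#' @export
setMethod("islands", "PeakSet", function(x) x@islands)

#' @rdname FragmentSet-class
#' @export
setGeneric("cellState", function(x) standardGeneric("cellState"))
setMethod("cellState", "FragmentSet", function(x) x@cellState)
setMethod("cellState", "PeakSet", function(x) x@cellState)

#' @rdname FragmentSet-class
#' @export
setGeneric("chipMark", function(x) standardGeneric("chipMark"))
setMethod("chipMark", "FragmentSet", function(x) x@chipMark)
setMethod("chipMark", "PeakSet", function(x) x@chipMark)

#' @rdname FragmentSet-class
#' @export
setGeneric("librarySize", function(x) standardGeneric("librarySize"))
setMethod("librarySize", "FragmentSet", function(x) x@librarySize)

#' @rdname GroundTruthManifest-class
#' @export
setGeneric("plantedDomains", function(x) standardGeneric("plantedDomains"))
setMethod("plantedDomains", "GroundTruthManifest", function(x) x@domains)

#' @rdname GroundTruthManifest-class
#' @export
setGeneric("geneAnnotation", function(x) standardGeneric("geneAnnotation"))
setMethod("geneAnnotation", "GroundTruthManifest", function(x) x@genes)

#' @rdname GroundTruthManifest-class
#' @export
setGeneric("sensitiveGenes", function(x) standardGeneric("sensitiveGenes"))
setMethod("sensitiveGenes", "GroundTruthManifest",
          function(x) x@sensitiveGenes)

#' @rdname GroundTruthManifest-class
#' @export
setGeneric("switchGenes", function(x) standardGeneric("switchGenes"))
setMethod("switchGenes", "GroundTruthManifest", function(x) x@switchGenes)

#' @rdname GroundTruthManifest-class
#' @export
setGeneric("stateLabels", function(x) standardGeneric("stateLabels"))
setMethod("stateLabels", "GroundTruthManifest", function(x) x@stateLabels)

## ---- show methods ----

setMethod("show", "FragmentSet", function(object) {
  cat("FragmentSet:", object@sampleId, "\n",
      " state:", object@cellState, " mark:", object@chipMark,
      " replicate:", object@replicate, "\n",
      " fragments:", object@librarySize, "\n")
})

setMethod("show", "PeakSet", function(object) {
  cat("PeakSet:", object@cellState, object@chipMark, "\n",
      " islands:", length(object@islands),
      " total width:", sum(GenomicRanges::width(object@islands)), "bp\n",
      " provenance:", paste(object@provenance, collapse = ", "), "\n")
})

setMethod("show", "GroundTruthManifest", function(object) {
  cat("GroundTruthManifest\n",
      " states:", paste(object@stateLabels, collapse = ", "), "\n",
      " planted domains:", length(object@domains), "\n",
      " genes:", length(object@genes), "\n",
      " sensitive genes:",
      paste(sprintf("%s=%d", names(object@sensitiveGenes),
                    lengths(object@sensitiveGenes)), collapse = ", "), "\n",
      " switch genes:", nrow(object@switchGenes), "\n")
})
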