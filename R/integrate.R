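## Integration module: the three-filter cascade joining differential
## binding, inhibitor sensitivity and between-state concordance, and the
## final switch report.

#' Run the three-filter cascade for one state
#'
#' For the state where binding is present/enriched: candidate genes are
#' those annotated to an enriched large-magnitude site of that state
#' (filter 1); filter 2 keeps genes upregulated by the inhibitor in that
#' state; filter 3 keeps genes whose between-state expression change is
#' concordant with the binding change — a gene with binding gained in the
#' contrast state must be significantly lower there, a gene with binding
#' lost must be significantly higher. Genes annotated to enriched sites of
#' both states are flagged ambiguous and excluded.
#'
#' @param sites Classified union sites (\code{GRanges} with mcols
#'   \code{siteId}, \code{class}).
#' @param siteGeneMap Output of \code{\link{annotateSites}}.
#' @param sensitiveUp Named list: state -> genes upregulated by the
#'   inhibitor in that state.
#' @param betweenFlagged Flagged between-state DE table (the \code{table}
#'   element of \code{\link{flagSensitive}} applied to
#'   \code{\link{betweenStateDE}}, contrast state over reference state).
#' @param state The state whose enriched sites seed the cascade.
#' @param enrichedClass Site class carrying that state's enrichment
#'   (\code{"A-enriched"} or \code{"B-enriched"}).
#' @param concordantDirection Required between-state direction:
#'   \code{"down"} when the state is the contrast (binding gained there),
#'   \code{"up"} when it is the reference (binding lost in the contrast).
#' @return List with \code{state}, \code{candidates} (per-gene flags and
#'   provenance) and \code{finalGenes}.
#' @export
runCascade <- function(sites, siteGeneMap, sensitiveUp, betweenFlagged,
                       state, enrichedClass, concordantDirection) {
  stopifnot(enrichedClass %in% c("A-enriched", "B-enriched"),
            concordantDirection %in% c("down", "up"))
  cls <- stats::setNames(mcols(sites)$class, mcols(sites)$siteId)
  map <- siteGeneMap
  map$class <- cls[map$siteId]
  enriched <- map[map$class == enrichedClass, , drop = FALSE]
  otherClass <- setdiff(c("A-enriched", "B-enriched"), enrichedClass)
  ambiguous <- intersect(enriched$geneId,
                         map$geneId[map$class == otherClass])
  if (length(ambiguous))
    message("excluding gene(s) annotated to enriched sites of both ",
            "states: ", paste(ambiguous, collapse = ", "))
  enriched <- enriched[!enriched$geneId %in% ambiguous, , drop = FALSE]
  if (!nrow(enriched)) {
    return(list(state = state,
                candidates = data.frame(
                  geneId = character(), siteId = character(),
                  distance = integer(), hasDifferentialPromoterPeak =
                    logical(), inhibitorSensitive = logical(),
                  concordantBetweenStates = logical(),
                  betweenLog2Fc = numeric(), betweenFdr = numeric()),
                finalGenes = character()))
  }
  ## one row per gene; keep the nearest seeding site as provenance
  ord <- order(enriched$geneId, enriched$distance)
  enriched <- enriched[ord, , drop = FALSE]
  cand <- enriched[!duplicated(enriched$geneId), , drop = FALSE]

  sens <- cand$geneId %in% sensitiveUp[[state]]
  bt <- betweenFlagged[match(cand$geneId, betweenFlagged$geneId), ]
  conc <- !is.na(bt$direction) & bt$direction == concordantDirection
  out <- data.frame(
    geneId = cand$geneId, siteId = cand$siteId,
    distance = cand$distance,
    hasDifferentialPromoterPeak = TRUE,
    inhibitorSensitive = sens,
    concordantBetweenStates = conc,
    betweenLog2Fc = bt$log2FoldChange, betweenFdr = bt$fdr,
    row.names = NULL, stringsAsFactors = FALSE)
  list(state = state, candidates = out,
       finalGenes = sort(out$geneId[sens & conc]))
}

#' Assemble the two-direction switch report
#'
#' Combines the cascades of the reference state A (binding lost in B, so
#' genes de-repressed in B) and the contrast state B (binding gained in B,
#' so genes silenced in B) into the final switch table, optionally with a
#' row-centred expression summary ready for heatmap rendering.
#'
#' @param resultA Cascade result for the reference state (enriched class
#'   \code{"A-enriched"}, concordant direction \code{"up"}).
#' @param resultB Cascade result for the contrast state.
#' @param conditionTPM Optional matrix of per-condition mean TPM
#'   (\code{\link{conditionMeanTPM}} without its \code{maxTPM} column).
#' @return List with \code{silencedInB}, \code{derepressedInB},
#'   \code{table} (per-gene provenance rows) and \code{expression}
#'   (row-centred TPM summary, or \code{NULL}).
#' @export
switchReport <- function(resultA, resultB, conditionTPM = NULL) {
  pick <- function(res, label) {
    d <- res$candidates[res$candidates$geneId %in% res$finalGenes, ,
                        drop = FALSE]
    if (nrow(d)) {
      d$panel <- label
      d$boundState <- res$state
    }
    d
  }
  tabA <- pick(resultA, "derepressedInB")
  tabB <- pick(resultB, "silencedInB")
  tab <- rbind(tabB, tabA)
  expr <- NULL
  if (!is.null(conditionTPM) && nrow(tab)) {
    m <- conditionTPM[tab$geneId, , drop = FALSE]
    m <- m[, colnames(m) != "maxTPM", drop = FALSE]
    expr <- m - rowMeans(m)
  }
  list(silencedInB = resultB$finalGenes,
       derepressedInB = resultA$finalGenes,
       table = tab, expression = expr)
}
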