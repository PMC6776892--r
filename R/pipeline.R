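## End-to-end pipeline: islands -> consensus -> co-occupancy ->
## differential binding -> annotation -> differential expression ->
## cascade -> switch report. Accepts either the in-memory output of
## simulateStudy() or a directory written by writeSimulation() (the same
## layout any real study would be staged in).

readStudyDir <- function(dir) {
  chromSizes <- readChromSizes(file.path(dir, "chrom.sizes"))
  genes <- readGeneAnnotation(file.path(dir, "annotation.bed"), chromSizes)
  rna <- readCounts(file.path(dir, "counts.tsv"),
                    file.path(dir, "sample_sheet.tsv"))
  beds <- list.files(dir, pattern = "_rep[0-9]+\\.bed$", full.names = TRUE)
  fragmentSets <- list()
  for (b in beds) {
    id <- sub("\\.bed$", "", basename(b))
    parts <- strsplit(id, "_")[[1]]
    rep <- as.integer(sub("rep", "", parts[length(parts)]))
    mark <- parts[length(parts) - 1L]
    state <- paste(parts[-c(length(parts) - 1L, length(parts))],
                   collapse = "_")
    gr <- readBed(b, chromSizes)
    fragmentSets[[id]] <- FragmentSet(gr, cellState = state,
                                      chipMark = mark, replicate = rep,
                                      sampleId = id)
  }
  states <- unique(rna$sampleSheet$state)
  list(chromSizes = chromSizes, genes = genes, rna = rna,
       fragmentSets = fragmentSets, states = states)
}

#' Run the full differential-binding/expression pipeline
#'
#' Executes the complete analysis for a pair of cellular states: per-
#' replicate island calling for both marks, per-state consensus merging,
#' the H3K27me3 co-occupancy filter, the union-site Poisson differential
#' test with large-magnitude thresholds, TSS annotation, within-state
#' inhibitor differential expression, between-state vehicle differential
#' expression, and the two-direction concordance cascade. Filter in/out
#' counts are narrated as messages.
#'
#' @param study Either the list returned by \code{\link{simulateStudy}} or
#'   a directory path written by \code{\link{writeSimulation}}.
#' @param stateA,stateB The reference (untransformed-like) and contrast
#'   (transformed-like) states; default the first and last state present.
#' @param ezh2Params,k27Params \linkS4class{IslandParams} for the two
#'   marks.
#' @param diffParams A \linkS4class{DiffParams}.
#' @param maxDistBp Promoter window around the TSS (default 5000).
#' @param deFdr,deLog2Fc,deMaxTpm Differential-expression thresholds
#'   (defaults 0.01, 1, 1), reused for the between-state comparison.
#' @param verbose Narrate filter counts (default TRUE).
#' @return List with \code{consensus} (per state, co-occupancy-filtered
#'   EZH2 \linkS4class{PeakSet}s), \code{sites} (classified union sites),
#'   \code{volcano}, \code{siteGeneMap}, \code{de} (per-state flagged
#'   inhibitor DE), \code{betweenDE}, \code{cascadeA}, \code{cascadeB}
#'   and \code{report}.
#' @export
runPipeline <- function(study, stateA = NULL, stateB = NULL,
                        ezh2Params = islandParams("EZH2"),
                        k27Params = islandParams("H3K27me3"),
                        diffParams = ezswitch::diffParams(),
                        maxDistBp = 5000L, deFdr = 0.01, deLog2Fc = 1,
                        deMaxTpm = 1, verbose = TRUE) {
  if (is.character(study)) study <- readStudyDir(study)
  chromSizes <- study$chromSizes
  genes <- if (!is.null(study$genes)) study$genes else
    geneAnnotation(study$manifest)
  rna <- study$rna
  states <- unique(rna$sampleSheet$state)
  if (is.null(stateA)) stateA <- states[1]
  if (is.null(stateB)) stateB <- states[length(states)]
  say <- function(...) if (verbose) message(sprintf(...))

  ## ---- islands and consensus per state ----
  consensus <- list()
  ezh2Frags <- list()
  for (s in c(stateA, stateB)) {
    perMark <- list()
    for (m in c("EZH2", "H3K27me3")) {
      pars <- if (m == "EZH2") ezh2Params else k27Params
      reps <- Filter(function(fs) fs@cellState == s && fs@chipMark == m,
                     study$fragmentSets)
      if (!length(reps)) stop("no fragment sets for ", s, "/", m)
      peaks <- lapply(reps, callSampleIslands, chromSizes = chromSizes,
                      params = pars)
      perMark[[m]] <- mergeReplicates(peaks)
      say("%s %s: %d replicate(s) -> %d consensus islands", s, m,
          length(reps), length(islands(perMark[[m]])))
      if (m == "EZH2")
        ezh2Frags[[s]] <- lapply(reps, deduplicateFragments,
                                 redundancyThreshold =
                                   pars@redundancyThreshold)
    }
    consensus[[s]] <- filterCooccupancy(perMark$EZH2, perMark$H3K27me3)
    say("%s: co-occupancy filter kept %d / %d EZH2 islands", s,
        length(islands(consensus[[s]])), length(islands(perMark$EZH2)))
  }

  ## ---- differential binding ----
  sites <- siteUnion(consensus[[stateA]], consensus[[stateB]])
  say("union of %s and %s consensus: %d sites", stateA, stateB,
      length(sites))
  classified <- classifySites(sites, ezh2Frags[[stateA]],
                              ezh2Frags[[stateB]], diffParams)
  sites <- classified$sites
  nCl <- table(factor(mcols(sites)$class,
                      c("A-enriched", "B-enriched", "unchanged")))
  say("large-magnitude sites: %d %s-enriched, %d %s-enriched, %d unchanged",
      nCl[1], stateA, nCl[2], stateB, nCl[3])

  ## ---- annotation ----
  siteGeneMap <- annotateSites(sites, genes, maxDistBp)
  say("site-to-TSS annotation: %d assignments within %d bp",
      nrow(siteGeneMap), maxDistBp)

  ## ---- expression ----
  geneLengths <- stats::setNames(width(genes), genes$geneId)
  tpm <- computeTPM(rna$counts, geneLengths)
  conditions <- paste(rna$sampleSheet$state, rna$sampleSheet$treatment,
                      sep = "_")
  condTPM <- conditionMeanTPM(tpm, conditions)

  de <- list()
  sensitiveUp <- list()
  for (s in c(stateA, stateB)) {
    veh <- rna$sampleSheet$sample[rna$sampleSheet$state == s &
                                  rna$sampleSheet$treatment == "vehicle"]
    trt <- rna$sampleSheet$sample[rna$sampleSheet$state == s &
                                  rna$sampleSheet$treatment == "EZH2i"]
    res <- nbTwoGroupTest(rna$counts, veh, trt)
    cond <- conditions %in% paste(s, c("vehicle", "EZH2i"), sep = "_")
    maxTpmState <- apply(
      conditionMeanTPM(tpm[, cond, drop = FALSE],
                       conditions[cond])[, "maxTPM", drop = FALSE],
      1, max)
    fl <- flagSensitive(res, maxTpmState, deFdr, deLog2Fc, deMaxTpm)
    de[[s]] <- fl
    sensitiveUp[[s]] <- fl$upregulated
    say("%s inhibitor response: %d up, %d down", s,
        length(fl$upregulated), length(fl$downregulated))
  }

  between <- betweenStateDE(rna$counts, rna$sampleSheet, stateA, stateB)
  vehCond <- conditions %in% paste(c(stateA, stateB), "vehicle", sep = "_")
  maxTpmBetween <- conditionMeanTPM(
    tpm[, vehCond, drop = FALSE], conditions[vehCond])[, "maxTPM"]
  betweenFlagged <- flagSensitive(between, maxTpmBetween, deFdr,
                                  deLog2Fc, deMaxTpm)$table

  ## ---- cascade ----
  cascadeA <- runCascade(sites, siteGeneMap, sensitiveUp, betweenFlagged,
                         state = stateA, enrichedClass = "A-enriched",
                         concordantDirection = "up")
  cascadeB <- runCascade(sites, siteGeneMap, sensitiveUp, betweenFlagged,
                         state = stateB, enrichedClass = "B-enriched",
                         concordantDirection = "down")
  for (cs in list(cascadeA, cascadeB))
    say("%s cascade: %d candidates -> %d sensitive -> %d final",
        cs$state, nrow(cs$candidates),
        sum(cs$candidates$inhibitorSensitive), length(cs$finalGenes))

  report <- switchReport(cascadeA, cascadeB, condTPM)
  list(stateA = stateA, stateB = stateB, consensus = consensus,
       sites = sites, volcano = classified$volcano,
       siteGeneMap = siteGeneMap, de = de, betweenDE = betweenFlagged,
       tpm = tpm, conditionTPM = condTPM,
       cascadeA = cascadeA, cascadeB = cascadeB, report = report)
}
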