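## Synthetic-study generator. Emulates the statistical structure of a
## two-mark ChIP-seq + inhibitor RNA-seq design over two to three cellular
## states: uniform background fragment coverage with broad enriched
## domains (shared and state-specific, the EZH2 domains nested inside
## wider H3K27me3 domains), negative-binomial RNA counts with planted
## inhibitor-responsive genes and state-concordant switch genes, and
## promoter methylation anti-correlated with inhibitor sensitivity.
## Everything planted is recorded in a GroundTruthManifest.

#' SimConfig: parameters of a synthetic study
#'
#' Holds every tunable of the generator. Defaults describe the study
#' conditions used throughout the package's validation: a 10 Mb genome in
#' two chromosomes, two cellular states with two ChIP replicates per mark,
#' 2e5 fragments per sample, 8-fold enrichment inside 10 kb domains, and
#' RNA counts at dispersion 0.05 with a planted inhibitor response of
#' 2 log2 units.
#'
#' @slot nChroms,chromLengthBp Genome shape.
#' @slot stateLabels Cellular states, reference (untransformed-like) first;
#'   2 or 3 states.
#' @slot replicatesPerMark ChIP replicates per state and mark.
#' @slot nGenes Number of genes placed (non-overlapping, both strands).
#' @slot backgroundRate Background fragment intensity, fragments per bp per
#'   million library fragments.
#' @slot enrichmentFactor Fold over background inside enriched domains.
#' @slot nCommonDomains,nStateSpecificDomains Planted intergenic domains
#'   shared by all states / private to each state.
#' @slot domainWidthBp Width of planted EZH2 domains (the paired
#'   H3K27me3 domain extends 2 kb beyond each edge).
#' @slot fragmentLengthBp Fixed sheared-fragment length.
#' @slot librarySize Nominal fragments per ChIP sample.
#' @slot deLog2fc Planted inhibitor-response effect (log2).
#' @slot switchLog2fc Planted between-state repression for switch genes.
#' @slot nbDispersion Negative-binomial dispersion of RNA counts.
#' @slot nSensitiveGenes Inhibitor-responsive genes planted per state
#'   (switch genes bound in that state are counted among them).
#' @slot nSwitchGenes Integer vector, one entry per state: number of switch
#'   genes whose promoter binding is private to that state.
#' @slot rnaReplicates RNA-seq replicates per state and treatment.
#' @slot methylationBetaParams List with elements \code{sensitive} and
#'   \code{insensitive}, each an (alpha, beta) pair for the promoter
#'   methylation Beta distribution.
#' @slot seed Root RNG seed; child streams are derived per sample so adding
#'   a sample never perturbs existing ones.
#' @aliases SimConfig
#' @export
setClass("SimConfig",
  slots = c(
    nChroms = "integer", chromLengthBp = "numeric",
    stateLabels = "character", replicatesPerMark = "integer",
    nGenes = "integer", backgroundRate = "numeric",
    enrichmentFactor = "numeric", nCommonDomains = "integer",
    nStateSpecificDomains = "integer", domainWidthBp = "integer",
    fragmentLengthBp = "integer", librarySize = "integer",
    deLog2fc = "numeric", switchLog2fc = "numeric",
    nbDispersion = "numeric", nSensitiveGenes = "integer",
    nSwitchGenes = "integer", rnaReplicates = "integer",
    methylationBetaParams = "list", seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nChroms < 1) msg <- c(msg, "nChroms must be >= 1")
  ns <- length(object@stateLabels)
  if (ns < 2 || ns > 3) msg <- c(msg, "2 or 3 states are supported")
  if (anyDuplicated(object@stateLabels))
    msg <- c(msg, "state labels must be unique")
  if (object@enrichmentFactor < 1)
    msg <- c(msg, "enrichmentFactor must be >= 1")
  if (object@domainWidthBp >= object@chromLengthBp)
    msg <- c(msg, "domainWidthBp must be smaller than chromLengthBp")
  if (length(object@nSwitchGenes) != ns)
    msg <- c(msg, "nSwitchGenes needs one entry per state")
  counts <- c(object@nGenes, object@nCommonDomains,
              object@nStateSpecificDomains, object@librarySize,
              object@replicatesPerMark, object@rnaReplicates,
              object@nSensitiveGenes, object@nSwitchGenes)
  if (any(counts < 0)) msg <- c(msg, "counts must be >= 0")
  if (!all(c("sensitive", "insensitive") %in%
           names(object@methylationBetaParams)))
    msg <- c(msg, "methylationBetaParams needs 'sensitive'/'insensitive'")
  if (length(msg)) msg else TRUE
})

#' Construct a SimConfig
#'
#' @param preset \code{"default"} (the noisy study conditions) or
#'   \code{"strong"} (large effects and low dispersion, for exact
#'   end-to-end recovery of planted switch genes).
#' @param ... Named slot overrides, see \linkS4class{SimConfig}.
#' @return A \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(seed = 7L)
#' cfg2 <- simConfig("strong", nGenes = 200L)
#' @export
simConfig <- function(preset = c("default", "strong"), ...) {
  preset <- match.arg(preset)
  args <- list(
    nChroms = 2L, chromLengthBp = 5e6,
    stateLabels = c("UT", "TR"), replicatesPerMark = 2L,
    nGenes = 500L, backgroundRate = 0.1,
    enrichmentFactor = 8, nCommonDomains = 30L,
    nStateSpecificDomains = 10L, domainWidthBp = 10000L,
    fragmentLengthBp = 200L, librarySize = 200000L,
    deLog2fc = 2, switchLog2fc = 3,
    nbDispersion = 0.05, nSensitiveGenes = 30L,
    nSwitchGenes = c(2L, 3L), rnaReplicates = 3L,
    methylationBetaParams = list(sensitive = c(2, 8),
                                 insensitive = c(8, 2)),
    seed = 1L)
  if (preset == "strong") {
    args$deLog2fc <- 3
    args$switchLog2fc <- 4
    args$nbDispersion <- 0.01
    args$enrichmentFactor <- 12
  }
  user <- list(...)
  unknown <- setdiff(names(user), names(args))
  if (length(unknown))
    stop("unknown SimConfig fields: ", paste(unknown, collapse = ", "))
  args[names(user)] <- user
  ints <- c("nChroms", "replicatesPerMark", "nGenes", "nCommonDomains",
            "nStateSpecificDomains", "domainWidthBp", "fragmentLengthBp",
            "librarySize", "nSensitiveGenes", "nSwitchGenes",
            "rnaReplicates", "seed")
  for (f in ints) args[[f]] <- as.integer(args[[f]])
  if (length(args$nSwitchGenes) == 1L)
    args$nSwitchGenes <- rep(args$nSwitchGenes, length(args$stateLabels))
  do.call(new, c(list("SimConfig"), args))
}

#' Derive a child RNG seed from a root seed and a label
#'
#' Stable polynomial hash of the label folded into the root seed, modulo
#' 2^31 - 1, so each (purpose, state, mark, replicate) gets its own stream
#' and adding samples never perturbs existing ones.
#'
#' @param seed Integer root seed.
#' @param label Character stream label.
#' @return Integer seed in [0, 2^31 - 2].
#' @export
deriveSeed <- function(seed, label) {
  h <- as.numeric(seed) %% 2147483647
  for (b in utf8ToInt(label)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Fraction of each chromosome reserved for genes (head) and for
## intergenic planted domains (tail); the buffer in between keeps
## intergenic domains > 5 kb away from any TSS.
.GENE_REGION_FRACTION <- 0.45
.DOMAIN_REGION_START <- 0.55
.K27_EXTENSION_BP <- 2000L
.DOMAIN_SLOT_GAP_BP <- 6000L

#' Simulate a genome layout with planted ground truth
#'
#' Places non-overlapping genes on both strands in the head of each
#' chromosome, plants intergenic enriched domains (shared and
#' state-specific) in the tail, plants a promoter domain directly over the
#' TSS of each switch gene in its bound state only, and assembles the
#' per-state inhibitor-sensitive gene sets. Every EZH2 domain is nested
#' inside a wider H3K27me3 domain.
#'
#' @param config A \linkS4class{SimConfig}.
#' @return List with \code{chromSizes} (named integer vector),
#'   \code{genes} (\code{GRanges}) and \code{manifest}
#'   (\linkS4class{GroundTruthManifest}).
#' @export
simulateGenome <- function(config) {
  validObject(config)
  chromSizes <- stats::setNames(
    rep(as.integer(config@chromLengthBp), config@nChroms),
    paste0("chr", seq_len(config@nChroms)))
  si <- Seqinfo(names(chromSizes), seqlengths = chromSizes)
  states <- config@stateLabels

  withSeed(deriveSeed(config@seed, "genome"), {
    ## ---- genes ----
    perChrom <- diff(floor(config@nGenes * (0:config@nChroms) /
                           config@nChroms))
    geneRegion <- floor(.GENE_REGION_FRACTION * config@chromLengthBp)
    maxGeneLen <- 3000L
    geneRows <- list()
    for (ci in seq_len(config@nChroms)) {
      n <- perChrom[ci]
      if (n == 0) next
      slotW <- floor(geneRegion / n)
      if (slotW < maxGeneLen + 200L)
        stop("too many genes for the genome size: ",
             "increase chromLengthBp or reduce nGenes")
      len <- sample(1000:3000, n, replace = TRUE)
      offset <- floor(runif(n, 1, slotW - len - 1))
      start <- (seq_len(n) - 1L) * slotW + offset
      geneRows[[ci]] <- data.frame(
        chrom = names(chromSizes)[ci], start = start,
        end = start + len,
        strand = sample(c("+", "-"), n, replace = TRUE))
    }
    geneDf <- do.call(rbind, geneRows)
    genes <- GRanges(geneDf$chrom,
                     IRanges::IRanges(geneDf$start + 1, geneDf$end),
                     strand = geneDf$strand, seqinfo = si)
    mcols(genes)$geneId <- sprintf("gene_%04d", seq_along(genes))
    if (!isDisjoint(genes)) stop("internal error: genes overlap")

    tssPos <- ifelse(as.character(strand(genes)) == "+",
                     start(genes), end(genes))

    ## ---- switch genes: spaced so promoter domains never collide ----
    nSwitchTotal <- sum(config@nSwitchGenes)
    switchIdx <- integer()
    if (nSwitchTotal > 0) {
      candidates <- sample(seq_along(genes))
      for (i in candidates) {
        if (length(switchIdx) == nSwitchTotal) break
        if (all(abs(i - switchIdx) >= 3L)) switchIdx <- c(switchIdx, i)
      }
      if (length(switchIdx) < nSwitchTotal)
        stop("could not place switch genes with sufficient separation; ",
             "reduce nSwitchGenes or increase nGenes")
    }
    switchState <- rep(states, config@nSwitchGenes)
    switchDf <- data.frame(
      geneId = genes$geneId[switchIdx],
      boundState = switchState,
      expressionDirection = rep("down", length(switchIdx)),
      stringsAsFactors = FALSE)

    ## ---- sensitive genes (switch genes of a state are included) ----
    sens <- list()
    for (s in states) {
      own <- switchDf$geneId[switchDf$boundState == s]
      pool <- setdiff(genes$geneId, switchDf$geneId)
      extra <- max(config@nSensitiveGenes - length(own), 0L)
      if (extra > length(pool))
        stop("nSensitiveGenes exceeds the number of available genes")
      sens[[s]] <- sort(c(own, sample(pool, extra)))
    }

    ## ---- intergenic domains ----
    w <- config@domainWidthBp
    slotPitch <- w + .DOMAIN_SLOT_GAP_BP
    regionStart <- ceiling(.DOMAIN_REGION_START * config@chromLengthBp)
    regionLen <- config@chromLengthBp - regionStart -
      .K27_EXTENSION_BP - 1L
    slotsPerChrom <- floor(regionLen / slotPitch)
    nIntergenic <- config@nCommonDomains +
      length(states) * config@nStateSpecificDomains
    if (nIntergenic > slotsPerChrom * config@nChroms)
      stop("too many domains for the genome size: ",
           "increase chromLengthBp or reduce domain counts")
    slotIds <- sample(slotsPerChrom * config@nChroms, nIntergenic)
    slotChrom <- (slotIds - 1L) %/% slotsPerChrom + 1L
    slotPos <- regionStart + ((slotIds - 1L) %% slotsPerChrom) * slotPitch +
      .K27_EXTENSION_BP
    domStates <- c(rep(paste(states, collapse = ","),
                       config@nCommonDomains),
                   rep(states, each = config@nStateSpecificDomains))
    domType <- c(rep("common", config@nCommonDomains),
                 rep(paste0("specific_", states),
                     each = config@nStateSpecificDomains))
    domId <- sprintf("%s_%03d", domType, stats::ave(
      seq_along(domType), domType, FUN = seq_along))

    ## ---- promoter domains for switch genes ----
    if (length(switchIdx)) {
      pStart <- pmax(tssPos[switchIdx] - w %/% 2L, 1L)
      pStart <- pmin(pStart, config@chromLengthBp - w)
      slotChrom <- c(slotChrom,
                     match(as.character(seqnames(genes)[switchIdx]),
                           names(chromSizes)))
      slotPos <- c(slotPos, pStart)
      domStates <- c(domStates, switchDf$boundState)
      domId <- c(domId, sprintf("promoter_%s", switchDf$geneId))
    }

    ## EZH2 domain + nested (wider) H3K27me3 domain per locus
    ez <- GRanges(names(chromSizes)[slotChrom],
                  IRanges::IRanges(slotPos, width = w), seqinfo = si)
    k27 <- GRanges(names(chromSizes)[slotChrom],
                   IRanges::IRanges(
                     pmax(slotPos - .K27_EXTENSION_BP, 1L),
                     pmin(slotPos + w - 1L + .K27_EXTENSION_BP,
                          as.integer(config@chromLengthBp))),
                   seqinfo = si)
    domains <- c(ez, k27)
    mcols(domains)$mark <- rep(c("EZH2", "H3K27me3"), each = length(ez))
    mcols(domains)$states <- rep(domStates, 2L)
    mcols(domains)$enrichment <- rep(config@enrichmentFactor,
                                     length(domains))
    mcols(domains)$domainId <- if (length(domains)) {
      paste0(rep(domId, 2L), "_", mcols(domains)$mark)
    } else character(0)
    domains <- sort(domains)
  })

  manifest <- new("GroundTruthManifest", domains = domains, genes = genes,
                  sensitiveGenes = sens, switchGenes = switchDf,
                  stateLabels = states)
  validObject(manifest)
  list(chromSizes = chromSizes, genes = genes, manifest = manifest)
}

domainsFor <- function(manifest, state, mark) {
  dom <- plantedDomains(manifest)
  hasState <- vapply(strsplit(dom$states, ",", fixed = TRUE),
                     function(s) state %in% s, logical(1))
  dom[dom$mark == mark & hasState]
}

#' Simulate ChIP fragments for one sample
#'
#' Fragment midpoints are drawn from a piecewise-constant intensity:
#' uniform background everywhere, multiplied by the planted enrichment
#' inside domains carrying the requested mark in the requested state.
#' Fragments have fixed length and are clipped to chromosome bounds.
#' The replicate index perturbs the derived seed (and jitters the library
#' size by up to 20 percent) while domain positions stay shared.
#'
#' @param manifest A \linkS4class{GroundTruthManifest}.
#' @param state,mark Labels; must exist in the manifest.
#' @param replicate Replicate index.
#' @param config The \linkS4class{SimConfig} used to build the manifest.
#' @return A \linkS4class{FragmentSet}.
#' @export
simulateChipFragments <- function(manifest, state, mark, replicate,
                                  config) {
  if (!state %in% stateLabels(manifest))
    stop("unknown state: ", state)
  if (!mark %in% c("EZH2", "H3K27me3"))
    stop("unknown mark: ", mark)
  si <- seqinfo(geneAnnotation(manifest))
  chromSizes <- seqlengths(si)
  genomeBp <- sum(as.numeric(chromSizes))
  dom <- reduce(domainsFor(manifest, state, mark))
  enr <- config@enrichmentFactor
  L <- config@fragmentLengthBp

  seed <- deriveSeed(config@seed,
                     sprintf("chip/%s/%s/%d", state, mark, replicate))
  gr <- withSeed(seed, {
    jitter <- runif(1, 0.8, 1.2)
    b <- config@backgroundRate * (config@librarySize / 1e6) * jitter
    if (config@librarySize == 0 || b == 0) {
      GRanges(seqinfo = si)
    } else {
      ## segment the genome into background and enriched pieces
      gaps <- GenomicRanges::gaps(dom)
      gaps <- gaps[strand(gaps) == "*"]
      segs <- c(granges(gaps), granges(dom))
      rate <- c(rep(b, length(gaps)), rep(b * enr, length(dom)))
      nSeg <- rpois(length(segs), rate * width(segs))
      segIdx <- rep(seq_along(segs), nSeg)
      midpoint <- floor(start(segs)[segIdx] +
                        runif(sum(nSeg)) * width(segs)[segIdx])
      chromLen <- chromSizes[as.character(seqnames(segs))][segIdx]
      fragStart <- pmax(midpoint - L %/% 2L, 1)
      fragEnd <- pmin(fragStart + L - 1, chromLen)
      fr <- GRanges(seqnames(segs)[segIdx],
                    IRanges::IRanges(fragStart, fragEnd),
                    seqinfo = si)
      sort(fr)
    }
  })
  FragmentSet(gr, cellState = state, chipMark = mark,
              replicate = as.integer(replicate))
}

#' Simulate an RNA-seq count matrix
#'
#' Counts are negative-binomial with gene base means spanning roughly four
#' orders of magnitude and per-sample library factors varying by up to 30
#' percent. Planted sensitive genes are multiplied by \code{2^deLog2fc} in
#' inhibitor-treated samples of their state; switch genes are repressed by
#' \code{2^switchLog2fc} in their bound state (so expression is
#' concordant with promoter-domain gain/loss between states).
#'
#' @param manifest A \linkS4class{GroundTruthManifest}.
#' @param design Sample sheet data.frame with columns \code{sample},
#'   \code{state}, \code{treatment} (\code{"vehicle"}/\code{"EZH2i"}),
#'   \code{replicate}; defaults to a full design with
#'   \code{config@rnaReplicates} replicates.
#' @param config The \linkS4class{SimConfig}.
#' @return List with \code{counts} (integer matrix genes x samples) and
#'   \code{sampleSheet}.
#' @export
simulateRnaseqCounts <- function(manifest, design = NULL, config) {
  states <- stateLabels(manifest)
  if (is.null(design)) {
    design <- expand.grid(replicate = seq_len(config@rnaReplicates),
                          treatment = c("vehicle", "EZH2i"),
                          state = states, stringsAsFactors = FALSE)
    design <- design[, c("state", "treatment", "replicate")]
    design$sample <- sprintf("%s_%s_rep%d", design$state,
                             design$treatment, design$replicate)
  }
  if (!all(design$treatment %in% c("vehicle", "EZH2i")))
    stop("treatment labels must be 'vehicle' or 'EZH2i'")
  if (!all(design$state %in% states))
    stop("design states must be present in the manifest")

  genes <- geneAnnotation(manifest)
  gid <- genes$geneId
  nG <- length(gid)
  sw <- switchGenes(manifest)
  sens <- sensitiveGenes(manifest)

  base <- withSeed(deriveSeed(config@seed, "rna/basemeans"), {
    b <- 10^runif(nG, -1, 3)
    special <- unique(c(unlist(sens), sw$geneId))
    b[match(special, gid)] <- runif(length(special), 80, 400)
    b
  })

  ## expected mean per gene per sample
  mu <- matrix(base, nrow = nG, ncol = nrow(design))
  rownames(mu) <- gid
  colnames(mu) <- design$sample
  for (j in seq_len(nrow(design))) {
    s <- design$state[j]
    ## switch genes: repressed in their bound state
    bound <- sw$geneId[sw$boundState == s]
    mu[match(bound, gid), j] <- mu[match(bound, gid), j] *
      2^(-config@switchLog2fc)
    ## sensitive genes: de-repressed by the inhibitor in their state
    if (design$treatment[j] == "EZH2i") {
      up <- sens[[s]]
      mu[match(up, gid), j] <- mu[match(up, gid), j] * 2^config@deLog2fc
    }
  }

  libFactors <- withSeed(deriveSeed(config@seed, "rna/libfactors"),
                         runif(nrow(design), 0.7, 1.3))
  counts <- matrix(0L, nrow = nG, ncol = nrow(design),
                   dimnames = list(gid, design$sample))
  for (j in seq_len(nrow(design))) {
    cj <- withSeed(deriveSeed(config@seed,
                              paste0("rna/counts/", design$sample[j])),
                   rnbinom(nG, mu = mu[, j] * libFactors[j],
                           size = 1 / config@nbDispersion))
    counts[, j] <- as.integer(cj)
  }
  list(counts = counts, sampleSheet = design)
}

#' Simulate promoter methylation and bisulphite clone matrices
#'
#' Inhibitor-sensitive genes draw their promoter methylation fraction from
#' the low-methylation Beta distribution, all other genes from the high
#' one, reflecting that densely methylated promoters stay silent when the
#' Polycomb mark is removed.
#'
#' @param manifest A \linkS4class{GroundTruthManifest}.
#' @param config The \linkS4class{SimConfig}.
#' @param cloneGenes Gene ids for which clones-by-CpGs Bernoulli matrices
#'   are emitted (default none).
#' @param nClones,nCpgs Clone matrix dimensions.
#' @return List with \code{table} (data.frame \code{geneId},
#'   \code{sensitive}, \code{methylation}) and \code{cloneMatrices}
#'   (named list of 0/1 matrices).
#' @export
simulateMethylation <- function(manifest, config, cloneGenes = character(),
                                nClones = 10L, nCpgs = 20L) {
  gid <- geneAnnotation(manifest)$geneId
  sensAll <- unique(unlist(sensitiveGenes(manifest)))
  isSens <- gid %in% sensAll
  pars <- config@methylationBetaParams
  meth <- withSeed(deriveSeed(config@seed, "methylation"), {
    m <- numeric(length(gid))
    m[isSens] <- rbeta(sum(isSens), pars$sensitive[1], pars$sensitive[2])
    m[!isSens] <- rbeta(sum(!isSens), pars$insensitive[1],
                        pars$insensitive[2])
    m
  })
  tab <- data.frame(geneId = gid, sensitive = isSens, methylation = meth,
                    stringsAsFactors = FALSE)
  clones <- list()
  for (g in cloneGenes) {
    i <- match(g, gid)
    if (is.na(i)) stop("unknown gene id: ", g)
    clones[[g]] <- withSeed(
      deriveSeed(config@seed, paste0("methylation/clones/", g)),
      matrix(rbinom(nClones * nCpgs, 1, meth[i]), nrow = nClones))
  }
  list(table = tab, cloneMatrices = clones)
}

#' Simulate a full study
#'
#' Convenience wrapper running \code{\link{simulateGenome}},
#' \code{\link{simulateChipFragments}} for every (state, mark, replicate),
#' \code{\link{simulateRnaseqCounts}} and
#' \code{\link{simulateMethylation}}.
#'
#' @param config A \linkS4class{SimConfig}.
#' @return List with \code{config}, \code{chromSizes}, \code{manifest},
#'   \code{fragmentSets} (named list), \code{rna} (counts + sampleSheet)
#'   and \code{methylation}.
#' @export
simulateStudy <- function(config = simConfig()) {
  genome <- simulateGenome(config)
  fragmentSets <- list()
  for (s in config@stateLabels)
    for (m in c("EZH2", "H3K27me3"))
      for (r in seq_len(config@replicatesPerMark)) {
        fs <- simulateChipFragments(genome$manifest, s, m, r, config)
        fragmentSets[[fs@sampleId]] <- fs
      }
  rna <- simulateRnaseqCounts(genome$manifest, config = config)
  meth <- simulateMethylation(genome$manifest, config)
  list(config = config, chromSizes = genome$chromSizes,
       manifest = genome$manifest, fragmentSets = fragmentSets,
       rna = rna, methylation = meth)
}

#' Write a simulated study to disk
#'
#' Emits the spec'd plain-text tree: one BED3 per ChIP sample
#' (\code{{state}_{mark}_rep{i}.bed}), \code{chrom.sizes},
#' \code{annotation.bed} (BED6, gene id in the name column),
#' \code{counts.tsv} + \code{sample_sheet.tsv}, \code{methylation.tsv}
#' and \code{manifest.json}. All coordinates are 0-based half-open.
#'
#' @param sim Output of \code{\link{simulateStudy}}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeChromSizes(sim$chromSizes, file.path(dir, "chrom.sizes"))
  for (fs in sim$fragmentSets)
    writeBed(fragments(fs), file.path(dir, paste0(fs@sampleId, ".bed")))
  genes <- geneAnnotation(sim$manifest)
  mcols(genes)$name <- genes$geneId
  mcols(genes)$score <- 0
  writeBed(genes, file.path(dir, "annotation.bed"), bed6 = TRUE)
  writeCounts(sim$rna$counts, sim$rna$sampleSheet,
              file.path(dir, "counts.tsv"),
              file.path(dir, "sample_sheet.tsv"))
  utils::write.table(sim$methylation$table,
                     file.path(dir, "methylation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeManifest(sim$manifest, file.path(dir, "manifest.json"))
  invisible(dir)
}
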