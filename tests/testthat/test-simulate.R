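test_that("the generator is deterministic and file outputs byte-identical", {
  cfg <- simConfig(seed = 5L, nGenes = 60L, nCommonDomains = 4L,
                   nStateSpecificDomains = 2L, librarySize = 20000L)
  s1 <- simulateStudy(cfg)
  s2 <- simulateStudy(cfg)
  expect_identical(s1$rna$counts, s2$rna$counts)
  expect_identical(fragments(s1$fragmentSets[[1]]),
                   fragments(s2$fragmentSets[[1]]))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  writeSimulation(s1, d1)
  writeSimulation(s2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     info = f)
})

test_that("adding a replicate never perturbs existing samples", {
  cfg <- simConfig(seed = 5L, nGenes = 60L, nCommonDomains = 4L,
                   nStateSpecificDomains = 2L, librarySize = 20000L)
  g <- simulateGenome(cfg)
  r1 <- simulateChipFragments(g$manifest, "UT", "EZH2", 1L, cfg)
  r2 <- simulateChipFragments(g$manifest, "UT", "EZH2", 2L, cfg)
  r1again <- simulateChipFragments(g$manifest, "UT", "EZH2", 1L, cfg)
  expect_identical(fragments(r1), fragments(r1again))
  expect_false(identical(fragments(r1), fragments(r2)))
})

test_that("manifest is consistent with the emitted annotation", {
  cfg <- simConfig(seed = 9L)
  g <- simulateGenome(cfg)
  man <- g$manifest
  dom <- plantedDomains(man)
  # domains inside chromosome bounds
  expect_true(all(GenomicRanges::start(dom) >= 1))
  expect_true(all(GenomicRanges::end(dom) <=
    GenomeInfoDb::seqlengths(dom)[as.character(
      GenomicRanges::seqnames(dom))]))
  # genes non-overlapping, both strands in play
  expect_true(IRanges::isDisjoint(geneAnnotation(man)))
  expect_setequal(unique(as.character(
    GenomicRanges::strand(geneAnnotation(man)))), c("+", "-"))

  # each switch gene has a promoter EZH2 domain overlapping its TSS in
  # exactly the declared state (independent scan of the manifest)
  sw <- switchGenes(man)
  expect_equal(nrow(sw), sum(cfg@nSwitchGenes))
  expect_equal(sum(sw$boundState == "TR"), cfg@nSwitchGenes[2])
  genes <- geneAnnotation(man)
  for (i in seq_len(nrow(sw))) {
    gi <- genes[genes$geneId == sw$geneId[i]]
    tss <- if (as.character(GenomicRanges::strand(gi)) == "+")
      GenomicRanges::start(gi) else GenomicRanges::end(gi)
    hits <- dom[dom$mark == "EZH2" &
                GenomicRanges::start(dom) <= tss &
                GenomicRanges::end(dom) >= tss &
                as.character(GenomicRanges::seqnames(dom)) ==
                  as.character(GenomicRanges::seqnames(gi))]
    expect_equal(unique(hits$states), sw$boundState[i])
  }
  # every EZH2 domain is nested in an H3K27me3 domain
  ez <- dom[dom$mark == "EZH2"]
  k27 <- dom[dom$mark == "H3K27me3"]
  within <- GenomicRanges::countOverlaps(ez, k27, type = "within") > 0
  expect_true(all(within))
})

test_that("nothing-planted configs yield empty truth", {
  cfg <- simConfig(seed = 2L, nGenes = 50L, nStateSpecificDomains = 0L,
                   nSwitchGenes = c(0L, 0L), nCommonDomains = 3L,
                   nSensitiveGenes = 0L, librarySize = 10000L)
  g <- simulateGenome(cfg)
  expect_equal(nrow(switchGenes(g$manifest)), 0)
  expect_true(all(vapply(sensitiveGenes(g$manifest), length, 0L) == 0))
  expect_true(all(plantedDomains(g$manifest)$states == "UT,TR"))
})

test_that("fragment counts conserve and background is homogeneous Poisson", {
  cfg <- simConfig(seed = 3L, nGenes = 40L, nCommonDomains = 0L,
                   nStateSpecificDomains = 0L, nSwitchGenes = c(0L, 0L),
                   nSensitiveGenes = 0L, librarySize = 100000L)
  g <- simulateGenome(cfg)
  fs <- simulateChipFragments(g$manifest, "UT", "EZH2", 1L, cfg)
  expect_equal(librarySize(fs), length(fragments(fs)))
  # chi-square goodness of fit of window counts against one Poisson mean
  wins <- windowCounts(fs, g$chromSizes, 5000L)
  counts <- S4Vectors::mcols(wins)$count
  lambda <- mean(counts)
  cuts <- unique(qpois(c(.2, .4, .6, .8), lambda))
  breaks <- c(-Inf, cuts, Inf)
  obs <- as.vector(table(cut(counts, breaks)))
  pr <- diff(ppois(c(-Inf, cuts, Inf), lambda))
  chi <- sum((obs - sum(obs) * pr)^2 / (sum(obs) * pr))
  expect_gt(pchisq(chi, df = length(obs) - 1, lower.tail = FALSE), 0.01)
})

test_that("in-domain coverage matches the planted enrichment", {
  # a domain with enrichment 8 at background 5 fragments/kb
  cfg <- simConfig(seed = 13L, nGenes = 40L, nCommonDomains = 1L,
                   nStateSpecificDomains = 0L, nSwitchGenes = c(0L, 0L),
                   nSensitiveGenes = 0L, chromLengthBp = 2e6,
                   nChroms = 1L, librarySize = 0L)
  cfg@librarySize <- as.integer(round(5 / 1000 / cfg@backgroundRate * 1e6))
  g <- simulateGenome(cfg)
  dom <- plantedDomains(g$manifest)
  ez <- dom[dom$mark == "EZH2"]
  fs <- simulateChipFragments(g$manifest, "UT", "EZH2", 1L, cfg)
  inDom <- sum(GenomicRanges::countOverlaps(
    ez, fragments(fs), minoverlap = 1L))
  expectBg <- 5 / 1000 * GenomicRanges::width(ez)   # background tags
  expected <- 8 * expectBg
  # library jitter is at most 20%, midpoint model adds edge effects of
  # one fragment length; allow 4 SD around the jittered expectation
  expect_lt(abs(inDom - expected), 0.25 * expected + 4 * sqrt(expected))
})

test_that("zero library size gives an empty FragmentSet", {
  cfg <- simConfig(seed = 4L, nGenes = 30L, librarySize = 0L,
                   nCommonDomains = 2L, nStateSpecificDomains = 0L,
                   nSwitchGenes = c(0L, 0L), nSensitiveGenes = 0L)
  g <- simulateGenome(cfg)
  fs <- simulateChipFragments(g$manifest, "UT", "EZH2", 1L, cfg)
  expect_equal(librarySize(fs), 0L)
})

test_that("RNA counts carry the planted effects at the right magnitude", {
  sim <- defaultStudy()
  cfg <- sim$config
  counts <- sim$rna$counts
  ss <- sim$rna$sampleSheet
  man <- sim$manifest
  sens <- setdiff(sensitiveGenes(man)$TR, switchGenes(man)$geneId)
  veh <- ss$sample[ss$state == "TR" & ss$treatment == "vehicle"]
  trt <- ss$sample[ss$state == "TR" & ss$treatment == "EZH2i"]
  ratio <- rowMeans(counts[sens, trt]) / pmax(rowMeans(counts[sens, veh]),
                                              1)
  # average planted response ~= 2^deLog2fc within NB noise
  expect_gt(median(log2(ratio)), cfg@deLog2fc - 1)
  expect_lt(median(log2(ratio)), cfg@deLog2fc + 1)
  # unplanted genes show no systematic inhibitor response
  other <- setdiff(rownames(counts), unlist(sensitiveGenes(man)))
  lfcOther <- log2(rowMeans(counts[other, trt]) + 0.5) -
    log2(rowMeans(counts[other, veh]) + 0.5)
  expect_lt(abs(median(lfcOther)), 0.3)
})

test_that("null inhibitor effect is calibrated downstream", {
  cfg <- simConfig(seed = 21L, deLog2fc = 0, nSensitiveGenes = 100L,
                   nSwitchGenes = c(0L, 0L), nGenes = 800L)
  g <- simulateGenome(cfg)
  rna <- simulateRnaseqCounts(g$manifest, config = cfg)
  ss <- rna$sampleSheet
  veh <- ss$sample[ss$state == "UT" & ss$treatment == "vehicle"]
  trt <- ss$sample[ss$state == "UT" & ss$treatment == "EZH2i"]
  de <- nbTwoGroupTest(rna$counts, veh, trt)
  frac <- mean(de$pValue < 0.05, na.rm = TRUE)
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.09)
})

test_that("methylation separates sensitive from insensitive genes", {
  sim <- defaultStudy()
  tab <- sim$methylation$table
  expect_true(all(tab$methylation >= 0 & tab$methylation <= 1))
  cmp <- compareGeneSets(
    data.frame(geneId = tab$geneId, methylation = tab$methylation),
    sensitive = tab$geneId[tab$sensitive],
    insensitive = tab$geneId[!tab$sensitive])
  expect_lt(cmp$meanSensitive, cmp$meanInsensitive)
  expect_lt(cmp$holmP, 1e-4)

  # clone matrices: per-gene mean tracks the planted fraction
  cfg <- sim$config
  gene <- tab$geneId[which.max(tab$methylation)]
  m <- simulateMethylation(sim$manifest, cfg, cloneGenes = gene,
                           nClones = 40L, nCpgs = 25L)
  frac <- tab$methylation[tab$geneId == gene]
  got <- mean(m$cloneMatrices[[gene]])
  se <- sqrt(frac * (1 - frac) / (40 * 25))
  expect_lt(abs(got - frac), 5 * se + 1e-3)
})

test_that("manifest JSON round trip is lossless", {
  sim <- defaultStudy()
  path <- withr::local_tempfile(fileext = ".json")
  writeManifest(sim$manifest, path)
  back <- readManifest(path)
  expect_identical(as.data.frame(plantedDomains(back)),
                   as.data.frame(plantedDomains(sim$manifest)))
  expect_identical(as.data.frame(geneAnnotation(back)),
                   as.data.frame(geneAnnotation(sim$manifest)))
  expect_identical(sensitiveGenes(back), sensitiveGenes(sim$manifest))
  expect_identical(switchGenes(back), switchGenes(sim$manifest))
})

test_that("infeasible layouts raise sizing errors", {
  expect_error(simulateGenome(simConfig(seed = 1L, nGenes = 5000L,
                                        chromLengthBp = 1e6)),
               "too many genes")
  expect_error(simulateGenome(simConfig(seed = 1L,
                                        nCommonDomains = 500L)),
               "too many domains")
  expect_error(simulateChipFragments(defaultStudy()$manifest, "XX",
                                     "EZH2", 1L, defaultStudy()$config),
               "unknown state")
})
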