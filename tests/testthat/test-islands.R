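chromSizes1 <- c(chr1 = 100000L)

test_that("deduplication keeps at most the redundancy threshold", {
  fs <- fragmentSetFrom0(rep("chr1", 5), rep(100, 5), rep(300, 5),
                         chromSizes1)
  expect_identical(librarySize(deduplicateFragments(fs, 1L)), 1L)
  expect_identical(librarySize(deduplicateFragments(fs, 2L)), 2L)
  distinct <- fragmentSetFrom0("chr1", c(0, 500, 900),
                               c(200, 700, 1100), chromSizes1)
  expect_identical(librarySize(deduplicateFragments(distinct, 1L)), 3L)
})

test_that("fragments land in one window by midpoint; counts conserve", {
  fs <- fragmentSetFrom0("chr1", 150, 350, chromSizes1)
  wins <- windowCounts(fs, chromSizes1, 200L)
  hit <- which(S4Vectors::mcols(wins)$count == 1)
  # midpoint 250 (0-based) -> window [200, 400)
  expect_equal(GenomicRanges::start(wins)[hit], 201L)
  expect_equal(GenomicRanges::end(wins)[hit], 400L)
  expect_equal(sum(S4Vectors::mcols(wins)$count), 1L)

  empty <- fragmentSetFrom0(character(), numeric(), numeric(), chromSizes1)
  expect_true(all(S4Vectors::mcols(
    windowCounts(empty, chromSizes1, 200L))$count == 0))

  ten <- fragmentSetFrom0(rep("chr1", 10), 200 + 0:9, 210 + 0:9,
                          chromSizes1)
  w10 <- windowCounts(ten, chromSizes1, 200L)
  expect_equal(max(S4Vectors::mcols(w10)$count), 10L)
  expect_equal(sum(S4Vectors::mcols(w10)$count), librarySize(ten))
})

test_that("a uniform run of hot windows forms one overwhelming island", {
  counts <- rep(20L, 10)
  wins <- windowFixture(counts)
  params <- islandParams("EZH2", effectiveGenomeFraction = 1)
  ps <- callIslands(wins, params, libraryForLambda(1, 10), 2000,
                    cellState = "UT")
  gr <- islands(ps)
  expect_length(gr, 1)
  expect_equal(GenomicRanges::start(gr), 1L)
  expect_equal(GenomicRanges::end(gr), 2000L)
  # total 200 vs expected 10: beyond any conventional significance
  expect_lt(S4Vectors::mcols(gr)$qValue, 1e-50)
})

test_that("the gap parameter splits or joins clusters as specified", {
  counts <- c(rep(9L, 5), rep(0L, 4), rep(9L, 5))  # 800 bp ineligible gap
  wins <- windowFixture(counts)
  lib <- libraryForLambda(1, length(counts))
  p400 <- islandParams("EZH2", gapSizeBp = 400L,
                       effectiveGenomeFraction = 1)
  p1000 <- islandParams("EZH2", gapSizeBp = 1000L,
                        effectiveGenomeFraction = 1)
  expect_length(islands(callIslands(wins, p400, lib, 2800)), 2)
  expect_length(islands(callIslands(wins, p1000, lib, 2800)), 1)
})

test_that("island calls equal exhaustive run enumeration on micro-fixtures", {
  set.seed(101)
  params0 <- islandParams("EZH2", effectiveGenomeFraction = 1)
  for (rep in 1:20) {
    n <- sample(3:10, 1)
    lambda <- sample(c(0.5, 1, 2), 1)
    counts <- rpois(n, lambda) + sample(0:12, n, replace = TRUE) *
      rbinom(n, 1, 0.4)
    gapW <- sample(1:3, 1)
    params <- islandParams("EZH2", gapSizeBp = gapW * 200L,
                           effectiveGenomeFraction = 1,
                           islandFdr = 0.05)
    wins <- windowFixture(counts)
    ps <- callIslands(wins, params, libraryForLambda(lambda, n), n * 200)
    orac <- oracleIslands(counts, lambda, params@eligibilityP, gapW, 0.05)
    gr <- islands(ps)
    if (is.null(orac) || nrow(orac) == 0) {
      expect_length(gr, 0)
    } else {
      expect_equal(length(gr), nrow(orac))
      expect_equal(GenomicRanges::start(gr),
                   (orac$firstWindow - 1L) * 200L + 1L)
      expect_equal(GenomicRanges::end(gr), orac$lastWindow * 200L)
      expect_equal(S4Vectors::mcols(gr)$fragmentCount,
                   orac$fragmentCount)
      expect_equal(S4Vectors::mcols(gr)$score, orac$score,
                   tolerance = 1e-9)
      expect_equal(log(S4Vectors::mcols(gr)$pValue), orac$logP,
                   tolerance = 1e-9)
    }
  }
})

test_that("larger gaps never increase and looser FDR never decreases islands", {
  set.seed(7)
  counts <- rpois(60, 1) + sample(0:15, 60, replace = TRUE) *
    rbinom(60, 1, 0.3)
  wins <- windowFixture(counts)
  lib <- libraryForLambda(1, 60)
  nAtGap <- vapply(c(200L, 400L, 800L, 1600L), function(g) {
    length(islands(callIslands(wins, islandParams(
      "EZH2", gapSizeBp = g, effectiveGenomeFraction = 1,
      islandFdr = 0.5), lib, 12000)))
  }, 0L)
  expect_true(all(diff(nAtGap) <= 0))
  nAtFdr <- vapply(c(1e-6, 1e-4, 1e-2, 0.5), function(f) {
    length(islands(callIslands(wins, islandParams(
      "EZH2", effectiveGenomeFraction = 1, islandFdr = f), lib, 12000)))
  }, 0L)
  expect_true(all(diff(nAtFdr) >= 0))
})

test_that("empty library warns and returns an empty PeakSet", {
  wins <- windowFixture(rep(0L, 5))
  expect_warning(
    ps <- callIslands(wins, islandParams("EZH2"), 0, 1000),
    "empty library")
  expect_length(islands(ps), 0)
})

test_that("consensus merging fuses gaps strictly below 250 bp", {
  # gap 150 (< 250): merged
  a <- peakSetFrom0("chr1", c(100, 350), c(200, 400))
  m <- mergeReplicates(list(a), 250L)
  expect_length(islands(m), 1)
  expect_equal(GenomicRanges::start(islands(m)), 101L)
  expect_equal(GenomicRanges::end(islands(m)), 400L)
  # gap exactly 250: NOT merged
  b <- peakSetFrom0("chr1", c(100, 450), c(200, 500))
  expect_length(islands(mergeReplicates(list(b), 250L)), 2)
  # gap 249: merged
  d <- peakSetFrom0("chr1", c(100, 449), c(200, 500))
  expect_length(islands(mergeReplicates(list(d), 250L)), 1)
})

test_that("merged islands sum counts and keep the max score", {
  a <- peakSetFrom0("chr1", 100, 200, score = 5)
  b <- peakSetFrom0("chr1", 150, 300, score = 9)
  m <- mergeReplicates(list(a, b))
  gr <- islands(m)
  expect_length(gr, 1)
  expect_equal(S4Vectors::mcols(gr)$fragmentCount, 20L)
  expect_equal(S4Vectors::mcols(gr)$score, 9)
  # idempotence on a set with no close pairs
  far <- peakSetFrom0("chr1", c(0, 5000), c(1000, 6000))
  expect_equal(GenomicRanges::granges(islands(mergeReplicates(list(far)))),
               GenomicRanges::granges(islands(far)))
  # mixed state errors
  expect_error(mergeReplicates(list(a, peakSetFrom0("chr1", 0, 100,
                                                    state = "TR"))),
               "state and mark")
})

test_that("co-occupancy keeps islands with strictly more than 25% overlap", {
  ez <- peakSetFrom0("chr1", 0, 1000)            # width 1000
  k27at251 <- peakSetFrom0("chr1", 0, 251, mark = "H3K27me3")
  k27at250 <- peakSetFrom0("chr1", 0, 250, mark = "H3K27me3")
  expect_length(islands(filterCooccupancy(ez, k27at251)), 1)
  expect_length(islands(filterCooccupancy(ez, k27at250)), 0)
  # zero overlap dropped; containment retained
  k27far <- peakSetFrom0("chr1", 5000, 6000, mark = "H3K27me3")
  expect_length(islands(filterCooccupancy(ez, k27far)), 0)
  k27wide <- peakSetFrom0("chr1", 0, 2000, mark = "H3K27me3")
  expect_length(islands(filterCooccupancy(ez, k27wide)), 1)
  expect_error(filterCooccupancy(ez, peakSetFrom0("chr1", 0, 500,
                                                  state = "TR",
                                                  mark = "H3K27me3")),
               "states")
})
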