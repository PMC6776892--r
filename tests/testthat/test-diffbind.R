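chromSizes1 <- c(chr1 = 100000L)

test_that("site union fuses overlaps and labels origins", {
  a <- peakSetFrom0("chr1", 0, 1000, state = "UT")
  b <- peakSetFrom0("chr1", 500, 1500, state = "TR")
  u <- siteUnion(a, b)
  expect_length(u, 1)
  expect_equal(GenomicRanges::start(u), 1L)
  expect_equal(GenomicRanges::end(u), 1500L)
  expect_equal(S4Vectors::mcols(u)$origin, "common")

  # disjoint -> two sites with their own origin; bookended not fused
  a2 <- peakSetFrom0("chr1", 0, 1000, state = "UT")
  b2 <- peakSetFrom0("chr1", 1000, 2000, state = "TR")
  u2 <- siteUnion(a2, b2)
  expect_length(u2, 2)
  expect_setequal(S4Vectors::mcols(u2)$origin, c("A-only", "B-only"))

  # identical sets -> all common
  u3 <- siteUnion(a, peakSetFrom0("chr1", 0, 1000, state = "TR"))
  expect_true(all(S4Vectors::mcols(u3)$origin == "common"))
})

test_that("normalized counts scale midpoints to the pooled depth", {
  # 50 fragments with midpoints inside [0, 1000)
  fs <- fragmentSetFrom0(rep("chr1", 50), seq(10, 500, length.out = 50),
                         seq(110, 600, length.out = 50), chromSizes1)
  site <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000))
  n <- normalizedCount(fs, site, normDepth = 50)
  expect_equal(n, 50 * 50 / 50)          # identity at depth = library
  expect_equal(normalizedCount(fs, site, normDepth = 25), 25)
  empty <- GenomicRanges::GRanges("chr1", IRanges::IRanges(90001, 99000))
  expect_equal(normalizedCount(fs, empty), 0)
  none <- fragmentSetFrom0(character(), numeric(), numeric(), chromSizes1)
  expect_error(normalizedCount(none, site), "zero")
})

test_that("Poisson differential test follows the fold/p contract", {
  eq <- poissonDiffTest(40, 40)
  expect_equal(eq$foldChange, 1)
  expect_gt(eq$pValue, 0.3)

  lo <- poissonDiffTest(0, 100)
  expect_equal(lo$foldChange, 1 / 101)
  expect_equal(lo$pValue, 1)            # P(X >= 0) = 1

  hi <- poissonDiffTest(300, 30)
  orac <- oraclePoissonLogTail(300, 30) / log(10)
  expect_lt(abs(hi$logP / log(10) - orac), 1e-6 * abs(orac))

  expect_error(poissonDiffTest(-1, 10), "non-negative")
})

test_that("classification thresholds are inclusive and the volcano caps", {
  sites <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1, 2001, 4001), width = 1000))
  S4Vectors::mcols(sites)$siteId <- paste0("s", 1:3)
  S4Vectors::mcols(sites)$origin <- "common"

  # build exact boundary cases through params with matching thresholds
  params <- diffParams()
  # site 1: A strongly enriched (fold >= 1.5, p << 1e-20)
  # site 2: fold passes but p fails
  # site 3: no change
  res <- classifyFromCounts(sites, normCountA = c(300, 12, 40),
                            normCountB = c(30, 7, 40), params)
  cls <- S4Vectors::mcols(res$sites)$class
  expect_equal(cls, c("A-enriched", "unchanged", "unchanged"))

  # fold boundary is inclusive: (2999+1)/(1999+1) is exactly 1.5 and the
  # Poisson p is far below 1e-20, so the site qualifies; one tag less and
  # the fold drops just under 1.5 and the site is unchanged
  stub <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
  S4Vectors::mcols(stub)$siteId <- "s"
  S4Vectors::mcols(stub)$origin <- "common"
  atFold <- classifyFromCounts(stub, 2999, 1999, diffParams())
  expect_equal(S4Vectors::mcols(atFold$sites)$foldAoverB, 1.5)
  expect_lt(S4Vectors::mcols(atFold$sites)$logPA, log(1e-20))
  expect_equal(S4Vectors::mcols(atFold$sites)$class, "A-enriched")
  below <- classifyFromCounts(stub, 2998, 1999, diffParams())
  expect_equal(S4Vectors::mcols(below$sites)$class, "unchanged")
  # p boundary is inclusive: with pMax set to the site's own p-value the
  # site still qualifies
  p0 <- exp(poissonLogUpperTail(2999, 1999)) * (1 + 1e-9)
  atP <- classifyFromCounts(stub, 2999, 1999, diffParams(pMax = p0))
  expect_equal(S4Vectors::mcols(atP$sites)$class, "A-enriched")
  overP <- classifyFromCounts(stub, 2999, 1999,
                              diffParams(pMax = p0 / 10))
  expect_equal(S4Vectors::mcols(overP$sites)$class, "unchanged")

  # volcano display floor: p below 1e-100 shown as 100, class unaffected
  deep <- classifyFromCounts(stub, 3000, 30, diffParams())
  expect_equal(deep$volcano$negLog10P, 100)
  expect_lt(S4Vectors::mcols(deep$sites)$logPA / log(10), -100)
  expect_equal(S4Vectors::mcols(deep$sites)$class, "A-enriched")
})

test_that("no site can be enriched in both directions", {
  set.seed(33)
  n <- 500
  sites <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(seq(1, by = 2000, length.out = n), width = 1000))
  S4Vectors::mcols(sites)$siteId <- sprintf("s%03d", 1:n)
  S4Vectors::mcols(sites)$origin <- "common"
  a <- rpois(n, 50) * sample(c(1, 10), n, replace = TRUE)
  b <- rpois(n, 50) * sample(c(1, 10), n, replace = TRUE)
  res <- classifyFromCounts(sites, a, b)
  m <- S4Vectors::mcols(res$sites)
  passA <- m$foldAoverB >= 1.5 & m$logPA <= log(1e-20)
  passB <- m$foldBoverA >= 1.5 & m$logPB <= log(1e-20)
  expect_false(any(passA & passB))
  expect_true(all(m$class %in% c("A-enriched", "B-enriched", "unchanged")))
})

test_that("fold change is invariant to a common depth scaling", {
  base <- poissonDiffTest(120, 40)
  scaled <- poissonDiffTest(120, 40, diffParams(normDepth = 1e8))
  expect_equal(base$foldChange, scaled$foldChange)
  # normalizedCount: doubling library and counts together cancels
  fs1 <- fragmentSetFrom0(rep("chr1", 40), seq(0, 390, by = 10),
                          seq(100, 490, by = 10), chromSizes1)
  fs2 <- fragmentSetFrom0(rep("chr1", 80), rep(seq(0, 390, by = 10), 2),
                          rep(seq(100, 490, by = 10), 2), chromSizes1)
  site <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 600))
  expect_equal(normalizedCount(fs1, site), normalizedCount(fs2, site))
})

test_that("replicate validation reports per-direction overlap fractions", {
  sites <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1, 2001, 4001), width = 500))
  S4Vectors::mcols(sites)$class <- c("A-enriched", "B-enriched",
                                     "unchanged")
  same <- peakSetFrom0("chr1", c(0, 2000), c(500, 2500))
  rv <- replicateValidation(sites, same)
  expect_equal(rv$fraction, c(1, 1))
  none <- peakSetFrom0("chr1", 90000, 95000)
  rv0 <- replicateValidation(sites, none)
  expect_equal(rv0$fraction, c(0, 0))
})
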