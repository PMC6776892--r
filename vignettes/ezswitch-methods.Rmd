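---
title: "ezswitch: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ezswitch: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ezswitch` identifies genes whose repression by the Polycomb complex is
rewired between two cellular states — typically an untransformed-like
reference and a transformed-like contrast — by integrating broad-mark
ChIP-seq, inhibitor RNA-seq and between-state expression into a single
concordance cascade. This vignette documents the statistical model behind
each stage, the parameters that matter, the numerical choices, and what
the synthetic validation does and does not establish.

## The island model for broad marks

EZH2 and H3K27me3 form megabase-scale, diffuse enrichment domains rather
than point-source peaks, so the caller works on fixed windows rather than
read pileups. Each chromosome is tiled into disjoint `windowSizeBp`
(default 200 bp) windows; a fragment contributes to exactly one window,
the one containing its midpoint. Midpoint assignment (rather than
overlap counting) keeps the total count equal to the library size, which
makes the window-count model exactly Poisson under a uniform background
and every downstream tail computation analytic.

The background mean per window is
$$\lambda = \frac{N \cdot w}{G \cdot f}$$
with $N$ the deduplicated library size, $w$ the window size, $G$ the
genome length and $f$ the effective (mappable) genome fraction, default
0.75. A window is *eligible* when its count reaches the smallest integer
whose Poisson upper tail at $\lambda$ is at most `eligibilityP` (0.2).
Islands are maximal runs of eligible windows in which consecutive
eligible windows are separated by at most `gapSizeBp` of ineligible
windows — 400 bp for EZH2 and 600 bp for the broader H3K27me3 by
default, reflecting the marks' characteristic granularity. The island
score sums $-\ln P(X \ge c_i \mid \lambda)$ over eligible windows; the
island p-value is the Poisson upper tail of the island's total fragment
count at mean $\lambda \times$ (windows spanned), and islands are
retained at Benjamini–Hochberg $q <$ `islandFdr` (1e-4).

This island statistic is a self-contained re-derivation of the classic
window-clustering approach to broad-mark calling: eligibility, gap
bridging and the aggregate-Poisson island test are parameter-compatible
with the established callers, but the FDR control here is plain BH
across candidate islands rather than any tool-specific score-distribution
procedure, and equivalence with any particular published implementation
is not claimed. The single-end extension length (`fragmentSizeBp`, 110)
is accepted for parameter compatibility but unused: the pipeline starts
from true fragment intervals, which already have their own extent.

All Poisson tails are computed in log space through the regularized
incomplete gamma function (`ppois(..., log.p = TRUE)`), so probabilities
far below double-precision underflow (1e-300 and beyond) remain exact on
the log scale; the test suite holds them to 1e-6 relative error in
log10(p) against an independent term-summation oracle.

## Consensus, co-occupancy, differential binding

Replicate island sets are unioned and intervals separated by strictly
less than 250 bp merged (fragment counts summed, the maximum constituent
score kept, minimum p retained as a conservative summary). EZH2 islands
are then required to overlap the union of the state's H3K27me3 islands
over strictly more than 25 % of their width — the co-occupancy filter
that restricts analysis to catalytically coherent Polycomb domains.

The two states' consensus sets are fused into union sites: islands
overlapping by at least 1 bp become one `common` interval spanning both
(bookended intervals stay separate); the rest keep their extent with
origin `A-only` / `B-only`. Signal per site is the normalized tag count:
pooled replicate fragment midpoints in the site, scaled to tags per 10⁷
pooled fragments. The published analysis names its differential tool but
not its normalization; tags-per-ten-million with a pseudocount of one
tag is adopted here and exposed in `diffParams()`.

The enrichment test treats the (rounded) normalized target count as a
Poisson observation at the background state's normalized count:
$$FC = \frac{t + 1}{b + 1}, \qquad
  p = P(X \ge \mathrm{round}(t) \mid \max(b, 1)).$$
Rounding preserves the count-like semantics of the statistic on the
normalized scale. Whether the original test was applied one- or
two-sided per site is not documented anywhere we could find; `ezswitch`
explicitly runs the test in both directions around the union and
classifies a site A-enriched iff $FC_{A/B} \ge 1.5$ **and**
$p_{A/B} \le 10^{-20}$, both inclusive, symmetrically for B, with the
(practically unreachable) double qualification resolved to `unchanged`.
Because the thresholds demand a 1.5-fold difference, reciprocal folds
cannot both exceed them, which makes the classification antisymmetric by
construction. Volcano output floors displayed p-values at 1e-100;
classification always uses the unfloored value.

A caution worth recording: normalized counts are not raw counts, so the
Poisson p-value understates sampling variance by the normalization
factor when libraries are much smaller than the normalization depth.
The paired fold-change requirement is what keeps the large-magnitude
call robust; the p threshold alone should not be interpreted as a
calibrated error rate.

## Annotation and enrichment

A site's distance to a TSS is zero when the TSS lies inside the site and
otherwise the distance to the nearer edge — edge-based, not
midpoint-based, matching the "peak overlaps the TSS" semantics. A site
is assigned *all* TSSs it contains; if it contains none, all TSSs at the
exact minimum distance (bp-equality ties, no tolerance) are kept, and
assignments beyond 5 kb are dropped. The annotation expects one TSS per
gene; for multi-isoform annotations the documented pre-processing
convention is to collapse to the most upstream TSS per gene before
import — a convention of this package, since the source analyses do not
state their choice.

Feature-class enrichment (CpG islands, lamina-associated domains)
compares differential against common sites with a two-tailed Fisher
exact test using the point-probability rule (the convention of the
mainstream implementations: sum all tables with fixed margins whose
probability does not exceed the observed table's, with a 1e-7 relative
tie tolerance). Gene-set overlaps use the upper-tail hypergeometric
test. Both are verified against brute-force enumeration over all margins
at small table totals.

## The expression engine

The differential-expression test is deliberately a minimal two-group
negative-binomial Wald test, authored for this package: size factors by
median-of-ratios over genes with all-nonzero counts; per-gene dispersion
by method of moments on normalized counts, shrunk 50/50 toward an
$\alpha_0 + \alpha_1/\mu$ mean–dispersion trend and floored at 1e-8; the
log2 fold change of pseudocounted (0.5) normalized group means; a
delta-method standard error
$\mathrm{SE} = \sqrt{v_A/(m_A+0.5)^2 + v_B/(m_B+0.5)^2}/\ln 2$ with
$v_g = (m_g + \alpha m_g^2)/n_g$; and a two-sided normal p-value with BH
adjustment over genes with nonzero total count. There is no Cox–Reid
adjustment, no fold-change shrinkage and no independent filtering. The
acceptance surface for this engine is therefore defined by behaviour,
not by equivalence to any published package: on a 5,000-gene null at
dispersion 0.05 with 3 vs 3 samples the p < 0.05 fraction must fall in
[0.03, 0.07], and planted four-fold genes at base mean ≥ 50 must be
recovered at FDR ≤ 0.01 with power ≥ 0.8. Both are asserted in the test
suite with Monte-Carlo tolerance bands.

Inhibitor-sensitive genes satisfy FDR ≤ 0.01, log₂FC ≥ 1 and maximum
per-condition mean TPM ≥ 1. "Maximal TPM across conditions" is read
literally as the maximum over *condition means*, not over individual
samples. The between-state comparison (vehicle vs vehicle) reuses the
same thresholds; the source analyses do not state separate ones, and the
choice is exposed in `runPipeline()`.

## The cascade and its conventions

For the state where binding is enriched, candidates are genes annotated
to a state-enriched large-magnitude site (filter 1), restricted to genes
upregulated by EZH2 inhibition in that state (filter 2), and finally to
genes whose between-state change is concordant — significantly lower in
the contrast state when binding was gained there, significantly higher
when binding was lost (filter 3). Only inhibitor-*upregulated* genes
enter filter 2: the cascade looks for genes whose repression depends on
the mark, and downregulated responders (indirect effects) play no role
in it. A gene annotated to enriched sites of both states — possible with
multi-peak promoters — is flagged, listed and excluded; the source
analyses never address this case, and silently assigning such a gene to
either direction would fabricate a conclusion. The direction labels
(`stateA` reference, `stateB` contrast) are explicit arguments rather
than hard-coded state names.

## Methylation and FISH scoring

Bisulphite clone matrices are summarized as methylated-over-non-missing
fractions per CpG, per clone and overall. Sensitive vs insensitive gene
sets are compared per cell line with an unpaired two-sided t-test;
pooled variance is used (the source legend does not state the variance
assumption; the gene sets are large and similarly dispersed, and the
choice is flagged here). Holm's step-down method corrects across the
family of cell lines.

RNA-FISH expression is scored as the mean of per-image foci/nuclei
ratios — mean of ratios, not pooled counts, matching "average across the
10 images". The printed band intervals ("0–0.5", "0.51–0.75", …) leave
(0.50, 0.51) undefined for a continuous mean, so the implementation
makes the bands half-open at 0.50 / 0.75 / 1.0: ≤ 0.50 → "−",
(0.50, 0.75] → "+", (0.75, 1.0] → "++", > 1.0 → "+++", a total monotone
step function whose boundary values are tested exactly. A field is
positive when its ratio strictly exceeds 0.8.

## The synthetic-study generator

The generator emulates the statistical structure of the study design —
two (optionally three) cellular states, two ChIP replicates per mark,
broad enriched domains over uniform background, EZH2 domains nested
inside wider H3K27me3 domains, inhibitor-responsive genes, and switch
genes whose promoter binding is private to one state with a concordant
between-state expression shift. Its defaults are the validation
conditions used throughout: a 10 Mb genome (two 5 Mb chromosomes), 500
genes, 2×10⁵ fragments per sample, 8-fold enrichment in 10 kb domains
(background λ ≈ 5.3 per 200 bp window), NB dispersion 0.05, a planted
inhibitor response of 2 log₂ units and a between-state switch of 3 log₂
units — magnitudes a strongly Polycomb-regulated developmental gene
exhibits in practice. The `"strong"` preset (3 and 4 log₂ units,
dispersion 0.01, 12-fold enrichment) is the noise-free fixture on which
end-to-end recovery of the planted switch genes must be exact; under the
noisy default the suite requires recall and precision ≥ 0.8. These sizes
keep the full test suite and the acceptance script comfortably fast
while leaving dozens of domains and hundreds of fragments per domain —
enough that the recovery criteria are statistically meaningful rather
than anecdotal.

Some generator conventions worth knowing:

* **RNG.** One root seed; every sample and table draws from a child
  stream derived by a stable label hash (`deriveSeed`), so adding a
  replicate never perturbs existing samples and identical configurations
  are byte-identical on disk.
* **Fragments.** Fixed 200 bp length, midpoints drawn from a
  piecewise-constant intensity (background everywhere, ×enrichment
  inside domains), clipped to chromosome bounds. Replicates share domain
  positions and differ only through their stream and a ±20 % library
  jitter, mirroring the high replicate concordance of real broad-mark
  ChIP.
* **Layout.** Genes occupy the head of each chromosome and intergenic
  planted domains the tail, with a buffer larger than the promoter
  window, so intergenic domains never annotate to genes and the planted
  cascade truth is unambiguous. Switch-gene promoter domains are
  centred on the TSS (distance 0); annotation edge cases are exercised
  separately by dedicated fixtures, not by the generator.
* **Methylation.** Sensitive genes draw promoter methylation from
  Beta(2, 8) and insensitive genes from Beta(8, 2), encoding the
  anti-correlation between dense promoter methylation and inhibitor
  response; clone matrices are Bernoulli samples of the per-gene
  fraction.

What passing on this generator does *not* show: the generator has no
mappability or copy-number artefacts, no GC or fragment-length biases,
no input-control structure, uniform background rather than chromatin-
state-dependent background, and a single TSS per gene. Results on real
data additionally depend on alignment, deduplication and blacklist
filtering upstream of this pipeline's entry point (fragment intervals),
and on annotation quality. The validation demonstrates that the
*machinery* is correct under its stated model, not that the model
captures every failure mode of real chromatin data.

## Numerical and degenerate-input conventions

* Coordinates are 0-based half-open in every file (BED convention) and
  1-based closed inside R (GenomicRanges convention); conversion happens
  only in the I/O layer.
* Islands snap to window boundaries; the last window of a chromosome may
  be short.
* An empty library yields an empty island set with a warning, not an
  error; an all-zero RNA sample yields zero TPM with a warning.
* `P(X ≥ 0) = 1` by convention, so a depleted target never produces a
  significant enrichment p-value in its own direction.
* Thresholds quoted with ≥ / ≤ are implemented inclusively everywhere
  (fold 1.5, p 1e-20, FDR 0.01, log₂FC 1, maxTPM 1, TSS distance 5 kb);
  strict inequalities (co-occupancy > 25 %, merge gap < 250 bp,
  positive field > 0.8) are implemented strictly, and all boundaries are
  pinned by tests.

## Known limitations

* The island caller's FDR is BH across candidate islands; tools with
  score-distribution FDRs will draw slightly different boundaries at
  marginal islands.
* The Poisson differential test inherits the normalized-count caveat
  above; treat the 1e-20 threshold as a selection rule, not an error
  rate.
* The DE engine's normal Wald approximation is slightly liberal at very
  low counts and n = 2; the TPM filter removes most of that regime from
  the sensitive sets.
* With three states the pipeline compares one pair per run; run it per
  transition for the full three-state picture.
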