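## Expression module: TPM, a two-group negative-binomial Wald test with
## median-of-ratios normalization and trend-shrunk method-of-moments
## dispersions, BH adjustment, and the inhibitor-sensitivity flags
## (FDR <= 0.01, |log2FC| >= 1, maxTPM >= 1).

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over \code{stats::p.adjust(method = "BH")}; \code{NA}
#' p-values propagate.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted q-values.
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Holm step-down adjustment
#'
#' Thin wrapper over \code{stats::p.adjust(method = "holm")}.
#'
#' @inheritParams bhAdjust
#' @return Adjusted p-values.
#' @export
holmAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}

#' Transcripts per million
#'
#' Per sample: \code{rate = count / length_kb}; \code{TPM = 1e6 * rate /
#' sum(rate)}. Columns of samples with any nonzero count sum to 1e6;
#' all-zero samples give all-zero TPM with a warning.
#'
#' @param counts Integer matrix genes x samples, rownames gene ids.
#' @param geneLengthsBp Named vector of gene lengths in bp (> 0), covering
#'   all genes in \code{counts}.
#' @return Numeric TPM matrix of the same shape.
#' @export
computeTPM <- function(counts, geneLengthsBp) {
  len <- geneLengthsBp[rownames(counts)]
  if (any(is.na(len))) stop("missing gene lengths")
  if (any(len <= 0)) stop("gene lengths must be > 0")
  rate <- counts / (len / 1000)
  tot <- colSums(rate)
  zero <- tot == 0
  if (any(zero)) {
    warning("all-zero sample(s): ",
            paste(colnames(counts)[zero], collapse = ", "))
    tot[zero] <- 1
  }
  sweep(rate, 2, tot, "/") * 1e6
}

medianOfRatiosSizeFactors <- function(counts) {
  ok <- rowSums(counts == 0) == 0
  if (!any(ok)) {
    warning("no gene with all-nonzero counts; ",
            "falling back to column-total size factors")
    sf <- colSums(counts)
    return(sf / exp(mean(log(sf))))
  }
  logGeoMean <- rowMeans(log(counts[ok, , drop = FALSE]))
  sf <- apply(counts[ok, , drop = FALSE], 2, function(col)
    exp(stats::median(log(col) - logGeoMean)))
  sf
}

## Method-of-moments dispersion shrunk 50/50 toward an a0 + a1/mean trend,
## floored at 1e-8.
estimateDispersions <- function(norm, groupA, groupB) {
  mA <- rowMeans(norm[, groupA, drop = FALSE])
  mB <- rowMeans(norm[, groupB, drop = FALSE])
  vA <- apply(norm[, groupA, drop = FALSE], 1, stats::var)
  vB <- apply(norm[, groupB, drop = FALSE], 1, stats::var)
  nA <- length(groupA); nB <- length(groupB)
  ## pooled within-group moment estimate
  num <- (nA - 1) * (vA - mA) + (nB - 1) * (vB - mB)
  den <- (nA - 1) * mA^2 + (nB - 1) * mB^2
  mom <- ifelse(den > 0, pmax(num / den, 0), NA_real_)
  mu <- (nA * mA + nB * mB) / (nA + nB)
  ## mean-dispersion trend alpha(mu) = a0 + a1 / mu
  use <- is.finite(mom) & mu > 1 & mom > 0 & mom < 10
  trend <- if (sum(use) >= 10) {
    fit <- stats::lm(mom[use] ~ I(1 / mu[use]))
    a <- pmax(stats::coef(fit), 0)
    a[1] + a[2] / mu
  } else {
    rep(stats::median(mom[is.finite(mom)], na.rm = TRUE), length(mu))
  }
  trend[!is.finite(trend)] <- 0
  momFilled <- ifelse(is.finite(mom), mom, trend)
  pmax(0.5 * momFilled + 0.5 * trend, 1e-8)
}

#' Two-group negative-binomial Wald test
#'
#' Size factors by median-of-ratios over all supplied samples; per-gene
#' dispersion by method-of-moments on normalized counts, shrunk 50/50
#' toward an \eqn{a_0 + a_1/\mu} mean-dispersion trend and floored at
#' 1e-8; \code{log2FoldChange} of pseudocounted (0.5) normalized group
#' means (\code{groupB} over \code{groupA}); Wald statistic from the NB
#' delta-method standard error with a two-sided normal p-value; BH
#' adjustment over genes with nonzero total count.
#'
#' @param counts Integer matrix genes x samples.
#' @param groupA Column names or indices of the reference group (>= 2).
#' @param groupB Column names or indices of the treated group (>= 2).
#' @return \code{data.frame} with \code{geneId}, \code{baseMeanA},
#'   \code{baseMeanB}, \code{log2FoldChange}, \code{pValue}, \code{fdr}.
#' @export
nbTwoGroupTest <- function(counts, groupA, groupB) {
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("each group needs at least 2 samples")
  sub <- counts[, c(groupA, groupB), drop = FALSE]
  a <- seq_along(groupA)
  b <- length(groupA) + seq_along(groupB)
  sf <- medianOfRatiosSizeFactors(sub)
  norm <- sweep(sub, 2, sf, "/")
  alpha <- estimateDispersions(norm, a, b)
  mA <- rowMeans(norm[, a, drop = FALSE])
  mB <- rowMeans(norm[, b, drop = FALSE])
  lfc <- log2((mB + 0.5) / (mA + 0.5))
  ## delta method on log2 of the pseudocounted group means
  vMeanA <- (mA + alpha * mA^2) / length(a)
  vMeanB <- (mB + alpha * mB^2) / length(b)
  se <- sqrt(vMeanA / (mA + 0.5)^2 + vMeanB / (mB + 0.5)^2) / log(2)
  z <- ifelse(se > 0, lfc / se, 0)
  p <- 2 * stats::pnorm(-abs(z))
  expressed <- rowSums(sub) > 0
  p[!expressed] <- NA_real_
  fdr <- rep(NA_real_, length(p))
  fdr[expressed] <- bhAdjust(p[expressed])
  data.frame(geneId = rownames(counts), baseMeanA = mA, baseMeanB = mB,
             log2FoldChange = lfc, pValue = p, fdr = fdr,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-condition mean TPM and its maximum
#'
#' @param tpm TPM matrix (genes x samples).
#' @param conditions Character vector, one condition label per column.
#' @return Matrix of per-condition mean TPM with an extra column
#'   \code{maxTPM}.
#' @export
conditionMeanTPM <- function(tpm, conditions) {
  stopifnot(length(conditions) == ncol(tpm))
  means <- sapply(unique(conditions), function(cond)
    rowMeans(tpm[, conditions == cond, drop = FALSE]))
  cbind(means, maxTPM = apply(means, 1, max))
}

#' Flag inhibitor-sensitive genes
#'
#' Upregulated set: \code{fdr <= maxFdr}, \code{log2FoldChange >=
#' minLog2Fc} and \code{maxTPM >= minMaxTpm} (all inclusive);
#' downregulated set symmetric with \code{log2FoldChange <= -minLog2Fc}.
#'
#' @param de Result of \code{\link{nbTwoGroupTest}}.
#' @param maxTpm Named vector of max-over-condition mean TPM per gene.
#' @param maxFdr,minLog2Fc,minMaxTpm Thresholds (defaults 0.01, 1, 1).
#' @return List with character vectors \code{upregulated} and
#'   \code{downregulated}, plus the annotated \code{table} carrying
#'   \code{maxTPM}, \code{sensitive} and \code{direction} columns.
#' @export
flagSensitive <- function(de, maxTpm, maxFdr = 0.01, minLog2Fc = 1,
                          minMaxTpm = 1) {
  mt <- maxTpm[de$geneId]
  up <- !is.na(de$fdr) & de$fdr <= maxFdr &
    de$log2FoldChange >= minLog2Fc & mt >= minMaxTpm
  down <- !is.na(de$fdr) & de$fdr <= maxFdr &
    de$log2FoldChange <= -minLog2Fc & mt >= minMaxTpm
  de$maxTPM <- unname(mt)
  de$sensitive <- up | down
  de$direction <- ifelse(up, "up", ifelse(down, "down", "none"))
  list(upregulated = de$geneId[up], downregulated = de$geneId[down],
       table = de)
}

#' Differential expression between the vehicle arms of two states
#'
#' Runs \code{\link{nbTwoGroupTest}} comparing the vehicle-treated samples
#' of two cellular states (state B over state A).
#'
#' @param counts Counts matrix.
#' @param sampleSheet data.frame with \code{sample}, \code{state},
#'   \code{treatment} columns.
#' @param stateA,stateB State labels (reference, contrast).
#' @return As \code{\link{nbTwoGroupTest}}.
#' @export
betweenStateDE <- function(counts, sampleSheet, stateA, stateB) {
  va <- sampleSheet$sample[sampleSheet$state == stateA &
                           sampleSheet$treatment == "vehicle"]
  vb <- sampleSheet$sample[sampleSheet$state == stateB &
                           sampleSheet$treatment == "vehicle"]
  nbTwoGroupTest(counts, va, vb)
}
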