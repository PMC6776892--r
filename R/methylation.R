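## Methylation and RNA-FISH module: bisulphite clone-matrix summaries,
## Holm-corrected comparison of sensitive vs insensitive gene sets, and
## the ordinal foci-per-nuclei scoring bands.

#' Summarize a bisulphite clone matrix
#'
#' Fractions are methylated calls over non-missing calls, per CpG, per
#' clone and overall. An all-missing CpG is reported as \code{NA} and
#' excluded from the overall fraction.
#'
#' @param cloneMatrix Matrix clones x CpGs with entries 0 (unmethylated),
#'   1 (methylated) or \code{NA} (missing).
#' @return List with \code{perCpg}, \code{perClone}, \code{overall}.
#' @export
cloneSummary <- function(cloneMatrix) {
  m <- as.matrix(cloneMatrix)
  if (!nrow(m)) stop("clone matrix needs at least one clone")
  if (any(!m %in% c(0, 1, NA)))
    stop("clone matrix entries must be 0, 1 or NA")
  perCpg <- colMeans(m, na.rm = TRUE)
  perCpg[colSums(!is.na(m)) == 0] <- NA_real_
  perClone <- rowMeans(m, na.rm = TRUE)
  overall <- mean(m, na.rm = TRUE)
  list(perCpg = perCpg, perClone = perClone, overall = overall)
}

#' Compare methylation of sensitive vs insensitive gene sets
#'
#' Per comparison (one per cell line / sample column): unpaired two-sided
#' Student's t-test with pooled variance between the two gene sets'
#' methylation values, with Holm's step-down correction across the family
#' of comparisons.
#'
#' @param methylation data.frame or matrix of per-gene methylation with
#'   gene ids as rownames (or a \code{geneId} column) and one numeric
#'   column per comparison.
#' @param sensitive,insensitive Character vectors of gene ids (each set
#'   needs >= 2 genes).
#' @return \code{data.frame} with \code{comparison}, group means,
#'   \code{t}, \code{pValue} and \code{holmP}.
#' @export
compareGeneSets <- function(methylation, sensitive, insensitive) {
  meth <- as.data.frame(methylation)
  if ("geneId" %in% names(meth)) {
    rownames(meth) <- meth$geneId
    meth$geneId <- NULL
    meth$sensitive <- NULL
  }
  if (length(sensitive) < 2 || length(insensitive) < 2)
    stop("each gene set needs at least 2 genes")
  missing <- setdiff(c(sensitive, insensitive), rownames(meth))
  if (length(missing)) stop("genes absent from the methylation table")
  out <- lapply(names(meth), function(cmp) {
    x <- meth[sensitive, cmp]
    y <- meth[insensitive, cmp]
    tt <- stats::t.test(x, y, var.equal = TRUE)
    data.frame(comparison = cmp, meanSensitive = mean(x),
               meanInsensitive = mean(y),
               t = unname(tt$statistic), pValue = tt$p.value)
  })
  df <- do.call(rbind, out)
  df$holmP <- holmAdjust(df$pValue)
  df
}

#' Score RNA-FISH foci counts into ordinal bands
#'
#' The mean foci-per-nuclei ratio across images maps to the bands
#' \code{-} (<= 0.50), \code{+} ((0.50, 0.75]), \code{++} ((0.75, 1.0])
#' and \code{+++} (> 1.0). The positive-field fraction is the share of
#' images with a ratio strictly above 0.8.
#'
#' @param foci,nuclei Integer vectors, one entry per scored image;
#'   every image needs \code{nuclei > 0}.
#' @param sampleId Optional label.
#' @return List with \code{sampleId}, \code{ratios}, \code{meanRatio},
#'   \code{band}, \code{positiveFieldFraction}.
#' @export
scoreFoci <- function(foci, nuclei, sampleId = NA_character_) {
  if (length(foci) != length(nuclei) || !length(foci))
    stop("need matching non-empty foci and nuclei vectors")
  if (any(nuclei <= 0))
    stop("images with zero nuclei cannot be scored")
  ratios <- foci / nuclei
  meanRatio <- mean(ratios)
  band <- if (meanRatio <= 0.50) "-" else if (meanRatio <= 0.75) "+"
    else if (meanRatio <= 1.0) "++" else "+++"
  list(sampleId = sampleId, ratios = ratios, meanRatio = meanRatio,
       band = band, positiveFieldFraction = mean(ratios > 0.8))
}
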