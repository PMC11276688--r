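## Rank-based tumor/normal differential expression. Paired designs use the
## Wilcoxon signed-rank test on pair differences, unpaired designs the rank-
## sum test; p-values are Benjamini-Hochberg adjusted. RNA counts go through
## median-of-ratios normalization before the same rank tests.

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper over \code{stats::p.adjust(method = "BH")}; inputs
#' outside \[0, 1\] are an error rather than silently clamped.
#'
#' @param pvalues numeric vector of p-values (NA allowed and propagated)
#' @return adjusted q-values, same order and length
#' @export
bhAdjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Parent protein symbol of ubiquitination-site ids
#'
#' Site ids follow the \code{GENE_K123} convention (lysine position appended
#' to the gene symbol).
#'
#' @param ids character site ids
#' @return parent gene symbols
#' @export
siteParent <- function(ids) sub("_K[0-9]+$", "", ids)

#' Rank-based tumor vs normal differential expression
#'
#' Per feature: a Wilcoxon signed-rank test on tumor-minus-normal pair
#' differences when \code{paired}, else a Wilcoxon rank-sum test; two-sided
#' p-values, BH-adjusted. log2FC is the mean of observed tumor values minus
#' the mean of observed normal values (inputs are log2-scale abundances).
#' Features with zero variance in both groups get p = 1 by convention;
#' paired features with fewer than 3 complete pairs get NA.
#'
#' @param matrix an \linkS4class{AbundanceExperiment}
#' @param paired use the signed-rank test over complete tumor/NAT pairs
#' @return data.frame with columns feature_id, log2FC, p, q, test, n_tumor,
#'   n_normal
#' @export
testDifferential <- function(matrix, paired = TRUE) {
  d <- sampleDesign(matrix)
  m <- abundance(matrix)
  tum <- d$sample_id[d$condition == "tumor"]
  nor <- d$sample_id[d$condition == "normal"]
  if (!length(tum) || !length(nor))
    stop("both tumor and normal samples are required")
  if (paired) {
    pairs <- completePairs(matrix)
    if (!nrow(pairs)) stop("paired test requested but no complete pairs found")
  }
  nfeat <- nrow(m)
  p <- numeric(nfeat); fc <- numeric(nfeat)
  nt <- integer(nfeat); nn <- integer(nfeat)
  for (i in seq_len(nfeat)) {
    xt <- m[i, tum]; xn <- m[i, nor]
    fc[i] <- mean(xt, na.rm = TRUE) - mean(xn, na.rm = TRUE)
    if (!is.finite(fc[i])) fc[i] <- 0
    nt[i] <- sum(!is.na(xt)); nn[i] <- sum(!is.na(xn))
    if (paired) {
      diffs <- m[i, pairs$tumor] - m[i, pairs$normal]
      diffs <- diffs[!is.na(diffs)]
      if (length(diffs) < 3) { p[i] <- NA_real_; next }
      if (all(diffs == 0)) { p[i] <- 1; next }
      p[i] <- suppressWarnings(
        wilcox.test(diffs, alternative = "two.sided")$p.value)
    } else {
      xt <- xt[!is.na(xt)]; xn <- xn[!is.na(xn)]
      if (!length(xt) || !length(xn)) { p[i] <- NA_real_; next }
      if (var(c(xt, xn)) == 0) { p[i] <- 1; next }
      p[i] <- suppressWarnings(
        wilcox.test(xt, xn, alternative = "two.sided")$p.value)
    }
  }
  data.frame(feature_id = rownames(m), log2FC = fc, p = p, q = bhAdjust(p),
             test = if (paired) "wilcoxon_signed_rank" else
               "wilcoxon_rank_sum",
             n_tumor = nt, n_normal = nn,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Median-of-ratios count normalization
#'
#' Per-sample size factors are the median, over features with all-positive
#' counts, of the ratio of the count to the feature's geometric mean across
#' samples; counts are divided by their sample's size factor.
#'
#' @param counts an \linkS4class{AbundanceExperiment} of nonnegative counts
#' @return the normalized \linkS4class{AbundanceExperiment}, with the size
#'   factors attached as attribute \code{"sizeFactors"}
#' @export
normalizeCounts <- function(counts) {
  m <- abundance(counts)
  if (any(m < 0, na.rm = TRUE)) stop("counts must be nonnegative")
  allpos <- rowSums(m > 0) == ncol(m) & !apply(m, 1, anyNA)
  if (!any(allpos))
    stop("no feature has all-positive counts; size factors undefined")
  lg <- log(m[allpos, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- apply(exp(sweep(lg, 1, geo)), 2, median)
  out <- AbundanceExperiment(sweep(m, 2, sf, `/`), sampleDesign(counts))
  attr(out, "sizeFactors") <- sf
  out
}

#' Differential expression of RNA counts
#'
#' Counts are median-of-ratios normalized, then tested with the same rank
#' tests as the proteome. log2FC uses pseudo-counted normalized group means,
#' log2((mean_tumor + 0.5) / (mean_normal + 0.5)).
#'
#' @param counts an \linkS4class{AbundanceExperiment} of raw counts
#' @param paired use the signed-rank test over complete pairs
#' @return data.frame as [testDifferential()]
#' @export
testRNA <- function(counts, paired = TRUE) {
  normed <- normalizeCounts(counts)
  de <- testDifferential(normed, paired = paired)
  m <- abundance(normed)
  d <- sampleDesign(normed)
  mt <- rowMeans(m[, d$sample_id[d$condition == "tumor"], drop = FALSE],
                 na.rm = TRUE)
  mn <- rowMeans(m[, d$sample_id[d$condition == "normal"], drop = FALSE],
                 na.rm = TRUE)
  de$log2FC <- log2((mt + 0.5) / (mn + 0.5))
  zero <- mt == 0 & mn == 0
  de$log2FC[zero] <- 0
  de$p[zero] <- 1
  de$q <- bhAdjust(de$p)
  de$test <- paste0("median_ratio+", de$test)
  de
}

#' Differential expression of ubiquitination sites
#'
#' Paired signed-rank tests on protein-corrected site abundances; identical
#' contract to \code{testDifferential(paired = TRUE)}. Site ids keep their
#' parent protein symbol in a \code{parent} column.
#'
#' @param sites an \linkS4class{AbundanceExperiment} of site abundances with
#'   a paired design
#' @return data.frame as [testDifferential()] plus a \code{parent} column
#' @export
testSites <- function(sites) {
  if (!nrow(completePairs(sites)))
    stop("site tests require a paired tumor/NAT design (signed-rank test)")
  de <- testDifferential(sites, paired = TRUE)
  de$parent <- siteParent(de$feature_id)
  de
}
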