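## Proteome-based prognosis: univariate Cox models per marker, maximally
## selected rank statistics for cutpoint selection with a permutation
## p-value, Kaplan-Meier/log-rank group comparison, biweight midcorrelation
## for robust co-expression, and between-group differential expression.

#' Univariate Cox proportional-hazards fit
#'
#' Partial-likelihood fit of survival on a single continuous covariate with
#' Efron tie handling (via the survival package); reports the log-hazard,
#' hazard ratio and Wald p-value.
#'
#' @param survival a [survivalTable()] data.frame
#' @param covariate per-sample numeric vector (defaults to the table's
#'   \code{marker} column)
#' @return one-row data.frame with beta, HR, se, p, n, events
#' @export
coxFit <- function(survival, covariate = survival$marker) {
  if (sum(survival$event) < 2) stop("at least 2 events are required")
  if (length(unique(covariate)) < 2) stop("covariate is constant")
  fit <- tryCatch(
    survival::coxph(survival::Surv(survival$time, survival$event) ~
                      covariate, ties = "efron"),
    warning = function(w) stop("Cox fit did not converge cleanly: ",
                               conditionMessage(w)))
  s <- summary(fit)
  data.frame(beta = unname(coef(fit)), HR = unname(exp(coef(fit))),
             se = unname(s$coefficients[, "se(coef)"]),
             p = unname(s$coefficients[, "Pr(>|z|)"]),
             n = nrow(survival), events = sum(survival$event))
}

## Log-rank (Savage) scores: event indicator minus the Nelson-Aalen
## cumulative hazard at the subject's own time.
.logrankScores <- function(time, event) {
  ev_times <- unique(time[event == 1])
  haz <- vapply(ev_times, function(t)
    sum(event == 1 & time == t) / sum(time >= t), numeric(1))
  cumhaz <- vapply(time, function(t)
    sum(haz[ev_times <= t]), numeric(1))
  event - cumhaz
}

#' Maximally selected rank statistics cutpoint
#'
#' For every candidate cutpoint (observed marker values within the quantile
#' window leaving at least \code{min_group} samples per side), the
#' standardized two-group log-rank statistic is computed from log-rank
#' scores; the cutpoint maximizing its absolute value is selected (smallest
#' value on ties). Because maximizing over cutpoints inflates significance,
#' the p-value is obtained by permuting the marker against the survival
#' data and recomputing the maximum each time, with add-one smoothing.
#'
#' @param survival a [survivalTable()] data.frame
#' @param marker per-sample numeric vector (defaults to the table's marker)
#' @param quantile_window candidate window as marker quantiles
#' @param min_group minimum group size on each side
#' @param n_perm permutation replicates
#' @param seed integer RNG seed
#' @return list with \code{cutpoint}, \code{max_stat}, \code{p},
#'   \code{n_high}, \code{n_low}, \code{candidates} and the per-candidate
#'   statistics \code{stats}
#' @export
maxstatCutpoint <- function(survival, marker = survival$marker,
                            quantile_window = c(0.1, 0.9), min_group = 5,
                            n_perm = 1000, seed = 1) {
  if (length(unique(marker)) < 2) stop("marker is constant")
  a <- .logrankScores(survival$time, survival$event)
  n <- length(a)
  qs <- quantile(marker, quantile_window)
  cand <- sort(unique(marker))
  cand <- cand[cand >= qs[1] & cand <= qs[2]]
  n_low <- vapply(cand, function(cp) sum(marker <= cp), numeric(1))
  keep <- n_low >= min_group & (n - n_low) >= min_group
  cand <- cand[keep]; n_low <- n_low[keep]
  if (!length(cand)) stop("no candidate cutpoints in the window")
  abar <- mean(a); ssq <- sum((a - abar)^2)
  stat_for <- function(scores) {
    ## S(cp) via cumulative sums over marker-sorted scores
    ord <- order(marker)
    cs <- cumsum(scores[ord])
    s <- cs[n_low]              # n_low-th sorted value = group size at cand
    (s - n_low * abar) /
      sqrt(n_low * (n - n_low) / (n * (n - 1)) * ssq)
  }
  tstat <- stat_for(a)
  obs_max <- max(abs(tstat))
  best <- which(abs(tstat) == obs_max)[1]
  p <- withSeed(seed, {
    null_max <- vapply(seq_len(n_perm), function(b)
      max(abs(stat_for(sample(a)))), numeric(1))
    (1 + sum(null_max >= obs_max)) / (n_perm + 1)
  })
  list(cutpoint = cand[best], max_stat = tstat[best], p = p,
       n_low = n_low[best], n_high = n - n_low[best],
       candidates = cand, stats = tstat)
}

#' Kaplan-Meier curves and log-rank comparison of two groups
#'
#' @param survival a [survivalTable()] data.frame
#' @param groups per-sample binary labels (factor/logical/character)
#' @return list with \code{chisq}, \code{p} and the survfit object
#'   \code{km}
#' @export
kmLogrank <- function(survival, groups) {
  g <- as.factor(groups)
  if (nlevels(droplevels(g)) < 2) stop("both groups must be nonempty")
  sv <- survival::Surv(survival$time, survival$event)
  sd_ <- survival::survdiff(sv ~ g)
  chisq <- unname(sd_$chisq)
  p <- pchisq(chisq, df = length(sd_$n) - 1, lower.tail = FALSE)
  list(chisq = chisq, p = p, km = survival::survfit(sv ~ g))
}

#' Biweight midcorrelation
#'
#' Robust correlation using Tukey biweights around the median: deviations
#' beyond 9 MADs get zero weight, so single gross outliers barely move the
#' estimate. Falls back to Pearson (with a warning) when either MAD is 0.
#'
#' @param x,y numeric vectors of equal length (>= 10)
#' @return correlation in \[-1, 1\]
#' @export
bicor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 10) stop("at least 10 observations are required")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  madx <- mad(x, constant = 1); mady <- mad(y, constant = 1)
  if (madx == 0 || mady == 0) {
    warning("zero MAD; falling back to Pearson correlation")
    return(cor(x, y))
  }
  wvec <- function(v, m) {
    u <- (v - median(v)) / (9 * m)
    (1 - u^2)^2 * (abs(u) < 1)
  }
  wx <- wvec(x, madx); wy <- wvec(y, mady)
  xs <- (x - median(x)) * wx
  ys <- (y - median(y)) * wy
  sum(xs * ys) / (sqrt(sum(xs^2)) * sqrt(sum(ys^2)))
}

#' Rank proteins by robust co-expression with a substrate
#'
#' Biweight midcorrelation of the substrate's abundance profile against
#' every other protein, ranked by absolute correlation (ties broken by
#' symbol) and truncated to the strongest \code{top_n}; the signed values
#' serve as DeltaE scores for [runSPIA()].
#'
#' @param substrate gene symbol present in the proteome
#' @param proteome an imputed \linkS4class{AbundanceExperiment}
#' @param top_n list length cap
#' @return data.frame with columns symbol, bicor (usable as
#'   \code{de_table} after renaming bicor to score)
#' @export
substrateAssociation <- function(substrate, proteome, top_n = 500) {
  m <- abundance(proteome)
  if (!substrate %in% rownames(m)) stop("substrate absent from proteome: ",
                                        substrate)
  target <- m[substrate, ]
  others <- setdiff(rownames(m), substrate)
  r <- vapply(others, function(f)
    suppressWarnings(bicor(target, m[f, ])), numeric(1))
  ord <- order(-abs(r), others)
  out <- data.frame(symbol = others[ord], bicor = r[ord],
                    stringsAsFactors = FALSE, row.names = NULL)
  head(out, top_n)
}

#' Between-group differential expression after cutpoint splitting
#'
#' Unpaired rank-sum tests of every protein between the high- and low-
#' marker groups (delegating to [testDifferential()]); log2FC is
#' high-group mean minus low-group mean. Returns the full table plus the
#' significant (q < 0.05) and pronounced (additionally |log2FC| >= 2)
#' subsets.
#'
#' @param proteome an \linkS4class{AbundanceExperiment}
#' @param high logical or 0/1 vector over the proteome's samples (TRUE =
#'   high-marker group)
#' @param sig_q significance level for the significant subset
#' @param pronounced_fc inclusive absolute log2FC bound for the pronounced
#'   subset
#' @return list with \code{table}, \code{significant}, \code{pronounced}
#' @export
groupDiffexp <- function(proteome, high, sig_q = 0.05, pronounced_fc = 2) {
  d <- sampleDesign(proteome)
  d$condition <- ifelse(as.logical(high), "tumor", "normal")
  d$pair_id <- NA_character_
  ae <- AbundanceExperiment(abundance(proteome), d)
  de <- testDifferential(ae, paired = FALSE)
  sig <- de[!is.na(de$q) & de$q < sig_q, , drop = FALSE]
  list(table = de, significant = sig,
       pronounced = sig[abs(sig$log2FC) >= pronounced_fc, , drop = FALSE])
}
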