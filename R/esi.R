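## E3-substrate correlation analysis: Spearman correlations of interacting
## pairs per condition, a matched random non-substrate background, and
## Kolmogorov-Smirnov comparison of correlation distributions.

.pairFrame <- function(pairs) {
  if (is(pairs, "ESINetwork")) esiEdges(pairs) else as.data.frame(pairs)
}

#' Spearman correlation of E3-substrate pairs
#'
#' For each edge, the Spearman correlation (average ranks on ties) of the
#' E3's and the partner's abundances over one condition's samples, using
#' pairwise-complete observations. Pairs with a member absent from the
#' matrix are skipped; correlations on fewer than \code{min_samples}
#' complete observations, or against a constant vector, are reported as NA.
#'
#' @param matrix an \linkS4class{AbundanceExperiment}
#' @param pairs an \linkS4class{ESINetwork} or a data.frame with columns
#'   e3, substrate
#' @param condition \code{"tumor"} or \code{"normal"}
#' @param min_samples minimum complete observations for a reported rho
#' @param is_substrate flag recorded in the output (FALSE for backgrounds)
#' @return data.frame with columns e3, partner, rho, n_samples, condition,
#'   is_substrate
#' @export
pairwiseSpearman <- function(matrix, pairs,
                             condition = c("tumor", "normal"),
                             min_samples = 10, is_substrate = TRUE) {
  condition <- match.arg(condition)
  edges <- .pairFrame(pairs)
  d <- sampleDesign(matrix)
  sel <- d$sample_id[d$condition == condition]
  m <- abundance(matrix)[, sel, drop = FALSE]
  present <- edges$e3 %in% rownames(m) & edges$substrate %in% rownames(m)
  if (any(!present))
    message(sum(!present), " pairs skipped: member absent from matrix")
  edges <- edges[present, , drop = FALSE]
  if (!nrow(edges))
    return(data.frame(e3 = character(), partner = character(),
                      rho = numeric(), n_samples = integer(),
                      condition = character(), is_substrate = logical(),
                      stringsAsFactors = FALSE))
  rho <- numeric(nrow(edges)); ns <- integer(nrow(edges))
  for (i in seq_len(nrow(edges))) {
    a <- m[edges$e3[i], ]; b <- m[edges$substrate[i], ]
    ok <- !is.na(a) & !is.na(b)
    ns[i] <- sum(ok)
    if (ns[i] < min_samples || var(a[ok]) == 0 || var(b[ok]) == 0) {
      rho[i] <- NA_real_
    } else {
      rho[i] <- cor(a[ok], b[ok], method = "spearman")
    }
  }
  data.frame(e3 = edges$e3, partner = edges$substrate, rho = rho,
             n_samples = ns, condition = condition,
             is_substrate = is_substrate, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Random non-substrate background for ESI correlations
#'
#' For every pair in \code{pairs}, draws one partner uniformly from the
#' matrix's proteins, excluding the E3 itself and all of its known
#' substrates (per the full \code{esi} network). The multiset of E3s is
#' preserved, so backgrounds are size- and enzyme-matched.
#'
#' @param pairs edges to match (ESINetwork or data.frame)
#' @param matrix the \linkS4class{AbundanceExperiment} defining eligible
#'   proteins
#' @param esi the full \linkS4class{ESINetwork} of known interactions
#' @param seed integer RNG seed
#' @return data.frame with columns e3, substrate (the random partner),
#'   source = "background"
#' @export
sampleRandomBackground <- function(pairs, matrix, esi, seed = 1) {
  edges <- .pairFrame(pairs)
  prots <- rownames(abundance(matrix))
  known <- split(esiEdges(esi)$substrate, esiEdges(esi)$e3)
  withSeed(seed, {
    partner <- character(nrow(edges)); keep <- logical(nrow(edges))
    for (i in seq_len(nrow(edges))) {
      e3 <- edges$e3[i]
      elig <- setdiff(prots, c(e3, known[[e3]]))
      if (!length(elig)) { keep[i] <- FALSE; next }
      partner[i] <- elig[sample.int(length(elig), 1)]
      keep[i] <- TRUE
    }
    if (any(!keep)) message(sum(!keep), " pairs skipped: no eligible partner")
    data.frame(e3 = edges$e3[keep], substrate = partner[keep],
               source = "background", stringsAsFactors = FALSE)
  })
}

#' Kolmogorov-Smirnov comparison of two correlation distributions
#'
#' Two-sample KS statistic D (the exact supremum of the ECDF difference)
#' with its asymptotic p-value, after dropping missing correlations.
#'
#' @param a,b [pairwiseSpearman()] tables, or bare numeric vectors
#' @return one-row data.frame with D, p, n_a, n_b
#' @export
compareDistributions <- function(a, b) {
  va <- if (is.numeric(a)) a else a$rho
  vb <- if (is.numeric(b)) b else b$rho
  va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
  if (!length(va) || !length(vb)) stop("empty correlation sample")
  ks <- suppressWarnings(ks.test(va, vb, exact = FALSE))
  data.frame(D = unname(ks$statistic), p = ks$p.value,
             n_a = length(va), n_b = length(vb))
}
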