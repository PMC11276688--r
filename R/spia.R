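## Signaling pathway impact analysis. Each pathway combines an
## over-representation p-value (pNDE, hypergeometric) with a topology-based
## perturbation p-value (pPERT): observed changes DeltaE propagate through
## the signed influence matrix as PF = DeltaE + B PF, the net accumulation
## Acc = PF - DeltaE sums to the total accumulation tA, and pPERT is the
## two-tailed bootstrap probability of a tA at least as extreme. The two are
## combined by Fisher's product method into pG.

#' Signed influence matrix of a pathway
#'
#' beta\[i, j\] is the sign of the edge j -> i (+1 activation, -1
#' inhibition, 0 absent); the normalized matrix B divides each column by the
#' source node's number of downstream targets, splitting its influence.
#'
#' @param graph a \linkS4class{PathwayGraph}
#' @return list with \code{beta}, \code{B} (both node x node matrices) and
#'   \code{n_ds} (per-node out-degree)
#' @export
buildInfluence <- function(graph) {
  nodes <- pathwayNodes(graph)
  if (!length(nodes)) stop("empty pathway")
  n <- length(nodes)
  beta <- matrix(0, n, n, dimnames = list(nodes, nodes))
  e <- pathwayEdges(graph)
  if (nrow(e))
    for (i in seq_len(nrow(e)))
      beta[e$target[i], e$source[i]] <- beta[e$target[i], e$source[i]] +
        e$sign[i]
  n_ds <- setNames(numeric(n), nodes)
  if (nrow(e)) {
    tab <- table(factor(e$source, levels = nodes))
    n_ds[names(tab)] <- as.numeric(tab)
  }
  B <- sweep(beta, 2, ifelse(n_ds > 0, n_ds, 1), `/`)
  B[, n_ds == 0] <- 0
  list(beta = beta, B = B, n_ds = n_ds)
}

#' Propagate observed changes through a pathway
#'
#' Solves PF = DeltaE + B PF, i.e. PF = (I - B)^-1 DeltaE. When I - B is
#' numerically singular (tight feedback loops), B is dampened to 0.99 B and
#' the solve retried.
#'
#' @param delta_e named numeric vector of observed log2FC per node (0 for
#'   nodes off the DE list); names must match the influence matrix
#' @param B normalized influence matrix from [buildInfluence()]
#' @return list with \code{delta_e}, \code{pf}, \code{acc} (= pf - delta_e)
#'   and \code{t_a} (= sum(acc))
#' @export
netPerturbation <- function(delta_e, B) {
  stopifnot(length(delta_e) == nrow(B))
  imb <- diag(nrow(B)) - B
  pf <- tryCatch(solve(imb, delta_e), error = function(e) NULL)
  if (is.null(pf) || rcond(imb) < 1e-12) {
    message("near-singular pathway system; dampening influence by 0.99")
    pf <- solve(diag(nrow(B)) - 0.99 * B, delta_e)
  }
  pf <- setNames(as.numeric(pf), rownames(B))
  acc <- pf - delta_e
  list(delta_e = delta_e, pf = pf, acc = acc, t_a = sum(acc))
}

#' Hypergeometric over-representation p-value of a pathway
#'
#' Upper-tail probability of observing at least \code{n_de_on_pathway}
#' differentially expressed members given the pathway and universe sizes.
#'
#' @param n_de_on_pathway observed DE members on the pathway
#' @param pathway_size measured pathway members
#' @param n_de_total size of the DE list
#' @param universe_size number of measured genes
#' @return p-value in \[0, 1\]
#' @export
pNDE <- function(n_de_on_pathway, pathway_size, n_de_total, universe_size) {
  if (n_de_on_pathway > min(pathway_size, n_de_total) ||
      pathway_size > universe_size || n_de_total > universe_size)
    stop("inconsistent counts")
  if (n_de_on_pathway == 0) return(1)
  phyper(n_de_on_pathway - 1, pathway_size, universe_size - pathway_size,
         n_de_total, lower.tail = FALSE)
}

## Linear reduction of tA: tA = sum((I-B)^-1 de - de) = w . de with
## w_j = colSums(M)_j - 1, M = (I-B)^-1. Lets the bootstrap draw node
## assignments without re-solving the system.
.tAWeights <- function(B) {
  imb <- diag(nrow(B)) - B
  if (rcond(imb) < 1e-12) imb <- diag(nrow(B)) - 0.99 * B
  m <- solve(imb)
  setNames(colSums(m) - 1, rownames(B))
}

#' Bootstrap perturbation p-value
#'
#' The observed DeltaE values are reassigned to NDE uniformly random
#' pathway nodes in each replicate and tA recomputed; pPERT is the
#' two-tailed empirical probability, centered at the null median, of a tA
#' at least as extreme as observed, with add-one smoothing.
#'
#' @param graph a \linkS4class{PathwayGraph}
#' @param delta_e named numeric vector: the observed values on their actual
#'   nodes (only nonzero entries are resampled)
#' @param n_boot bootstrap replicates
#' @param seed integer RNG seed
#' @return list with \code{p_pert}, \code{t_a_obs} and \code{t_a_null}
#' @export
pPert <- function(graph, delta_e, n_boot = 2000, seed = 1) {
  inf <- buildInfluence(graph)
  nodes <- pathwayNodes(graph)
  de <- setNames(numeric(length(nodes)), nodes)
  de[names(delta_e)] <- delta_e
  vals <- de[de != 0]
  nde <- length(vals)
  if (nde < 1) stop("at least one DE node is required")
  if (nde > length(nodes)) stop("NDE exceeds pathway size")
  w <- .tAWeights(inf$B)
  t_obs <- sum(w * de)
  t_null <- withSeed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(length(nodes), nde)
      sum(w[idx] * vals)
    }, numeric(1))
  })
  med <- median(t_null)
  p <- (1 + sum(abs(t_null - med) >= abs(t_obs - med))) / (n_boot + 1)
  list(p_pert = p, t_a_obs = t_obs, t_a_null = t_null)
}

#' Fisher product combination of two p-values
#'
#' pG = c - c log c with c = pNDE * pPERT, the tail probability of the
#' product of two independent uniforms (equivalently the chi-square_4 tail
#' of -2 log c).
#'
#' @param p_nde,p_pert p-values in (0, 1\]
#' @return combined p-value in (0, 1\]
#' @export
combineFisher <- function(p_nde, p_pert) {
  if (any(c(p_nde, p_pert) > 1)) stop("p-values must be <= 1")
  cc <- p_nde * p_pert
  if (cc <= 0) {
    message("zero combined p clamped to machine minimum")
    cc <- .Machine$double.xmin
  }
  cc - cc * log(cc)
}

#' Run pathway impact analysis over a pathway collection
#'
#' For each pathway, counts DE members (NDE), computes pNDE, propagates the
#' observed scores for tA and pPERT, and combines into pG; BH and
#' Bonferroni adjustments are applied across pathways. A pathway with no DE
#' member is reported with pNDE = 1, tA = 0, pPERT = 1. The score column
#' may hold any signed per-gene quantity (log2FC, robust correlations, ...).
#'
#' @param de_table data.frame with columns \code{symbol} and \code{score}
#'   (the DeltaE values); symbols must be measured
#' @param all_measured character, the measured-gene universe
#' @param pathways list of \linkS4class{PathwayGraph}
#' @param n_boot bootstrap replicates for pPERT
#' @param seed integer RNG seed
#' @return data.frame with pathway_id, NDE, pathway_size, pNDE, tA, pPERT,
#'   pG, q (BH), bonferroni, status; plus evidence-plot coordinates
#'   \code{minus_log_pNDE}, \code{minus_log_pPERT}
#' @export
runSPIA <- function(de_table, all_measured, pathways, n_boot = 2000,
                    seed = 1) {
  if (!length(pathways)) stop("empty pathway list")
  if (length(setdiff(de_table$symbol, all_measured)))
    stop("DE symbols must be a subset of the measured universe")
  scores <- setNames(de_table$score, de_table$symbol)
  rows <- lapply(seq_along(pathways), function(k) {
    g <- pathways[[k]]
    meas <- intersect(pathwayNodes(g), all_measured)
    hits <- intersect(meas, de_table$symbol)
    nde <- length(hits)
    if (nde == 0) {
      return(data.frame(pathway_id = pathwayId(g), NDE = 0L,
                        pathway_size = length(meas), pNDE = 1, tA = 0,
                        pPERT = 1, stringsAsFactors = FALSE))
    }
    pn <- pNDE(nde, length(meas), nrow(de_table), length(all_measured))
    pp <- pPert(g, scores[hits], n_boot = n_boot, seed = seed + k)
    data.frame(pathway_id = pathwayId(g), NDE = nde,
               pathway_size = length(meas), pNDE = pn, tA = pp$t_a_obs,
               pPERT = pp$p_pert, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$pG <- mapply(combineFisher, out$pNDE, out$pPERT)
  out$q <- bhAdjust(out$pG)
  out$bonferroni <- pmin(out$pG * nrow(out), 1)
  out$status <- ifelse(out$tA > 0, "Activated", "Inhibited")
  out$minus_log_pNDE <- -log(out$pNDE)
  out$minus_log_pPERT <- -log(out$pPERT)
  out[order(out$pG), ]
}
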