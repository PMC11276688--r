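## Tissue-specificity analysis of samples across cohorts: per-cohort Z-score
## normalization, retention of features shared by every cohort, PCA with
## JackStraw component selection, and Louvain clustering on a shared-nearest-
## neighbor graph.

.asCohortList <- function(matrices) {
  if (is(matrices, "AbundanceExperiment")) {
    d <- sampleDesign(matrices)
    matrices <- lapply(split(d$sample_id, d$cohort),
                       function(s) matrices[, s])
  }
  if (!length(matrices)) stop("no cohorts supplied")
  matrices
}

#' Per-cohort Z-score normalization of one condition
#'
#' For each cohort, the requested condition's samples are extracted and each
#' feature is centered and scaled by that cohort's own mean and SD, removing
#' cohort batch offsets. Cohorts are then concatenated on their shared
#' features. A feature with zero SD within a cohort is set to 0 there.
#'
#' @param matrices an \linkS4class{AbundanceExperiment} covering >= 2
#'   cohorts, or a list of per-cohort AbundanceExperiments
#' @param condition \code{"tumor"} or \code{"normal"}
#' @return merged \linkS4class{AbundanceExperiment} over the condition's
#'   samples and the shared features
#' @export
zscoreByCohort <- function(matrices, condition = c("tumor", "normal")) {
  condition <- match.arg(condition)
  matrices <- .asCohortList(matrices)
  if (length(matrices) < 2) stop("at least 2 cohorts are required")
  blocks <- lapply(matrices, function(ae) {
    d <- sampleDesign(ae)
    sel <- d$sample_id[d$condition == condition]
    if (length(sel) < 2)
      stop("cohort with fewer than 2 '", condition,
           "' samples: SD undefined")
    m <- abundance(ae)[, sel, drop = FALSE]
    mu <- rowMeans(m, na.rm = TRUE)
    sdv <- apply(m, 1, sd, na.rm = TRUE)
    z <- (m - mu) / sdv
    flat <- !is.na(sdv) & sdv == 0
    if (any(flat)) {
      z[flat, ] <- 0
      message(sum(flat), " zero-SD features set to 0 in a cohort")
    }
    list(z = z, design = d[d$sample_id %in% sel, , drop = FALSE])
  })
  shared <- Reduce(intersect, lapply(blocks, function(b) rownames(b$z)))
  if (!length(shared)) stop("no shared features across cohorts")
  AbundanceExperiment(
    do.call(cbind, lapply(blocks, function(b) b$z[shared, , drop = FALSE])),
    do.call(rbind, lapply(blocks, `[[`, "design")))
}

#' Catalog features present in every cohort
#'
#' Restricts the enzyme catalog to features observed (at least one
#' non-missing value) in every cohort, the retention rule behind
#' cross-cancer expression comparisons.
#'
#' @param matrices as in [zscoreByCohort()]
#' @param catalog an \linkS4class{EnzymeCatalog}
#' @param which \code{"e3"} or \code{"dub"}
#' @return character vector of retained symbols
#' @export
intersectFeatures <- function(matrices, catalog, which = c("e3", "dub")) {
  which <- match.arg(which)
  matrices <- .asCohortList(matrices)
  if (length(matrices) < 2) stop("at least 2 cohorts are required")
  want <- if (which == "e3") e3Symbols(catalog) else dubSymbols(catalog)
  present <- lapply(matrices, function(ae) {
    m <- abundance(ae)
    rownames(m)[rowSums(!is.na(m)) > 0]
  })
  out <- intersect(want, Reduce(intersect, present))
  if (!length(out)) stop("no catalog features shared by all cohorts")
  out
}

#' PCA with JackStraw component significance
#'
#' Runs PCA (samples as observations, features as variables), then builds a
#' null loading distribution by permuting a small random fraction of
#' features across samples in each replicate and re-running PCA. Per
#' component, each observed feature loading is converted to an empirical
#' p-value against the pooled null magnitudes, and the component p-value is
#' a one-sided KS test of those feature p-values against uniform (structure
#' shows up as an excess of small feature p-values).
#'
#' @param matrix an \linkS4class{AbundanceExperiment} (features x samples)
#'   or a plain numeric matrix in the same orientation
#' @param n_components number of components to assess
#' @param perm_frac fraction of features permuted per replicate
#' @param n_perm number of permutation replicates
#' @param alpha component significance level
#' @param seed integer RNG seed
#' @return list with \code{scores} (samples x components), \code{loadings}
#'   (features x components), \code{component_pvalues} and
#'   \code{significant_components}
#' @export
jackstraw <- function(matrix, n_components = 10, perm_frac = 0.01,
                      n_perm = 100, alpha = 0.05, seed = 1) {
  m <- if (is(matrix, "AbundanceExperiment")) abundance(matrix) else
    as.matrix(matrix)
  x <- t(m)                     # samples x features
  n_components <- min(n_components, dim(x) - 1L)
  n_feat <- ncol(x)
  n_shuf <- max(1L, floor(perm_frac * n_feat))
  if (perm_frac * n_feat < 1 && perm_frac > 0)
    message("perm_frac below one feature; using 1 feature per replicate")
  if (n_shuf < 1) stop("perm_frac too small: no feature to permute")
  pc <- prcomp(x, center = TRUE, scale. = FALSE, rank. = n_components)
  obs_load <- pc$rotation
  withSeed(seed, {
    null_load <- vector("list", n_perm)
    for (b in seq_len(n_perm)) {
      idx <- sample.int(n_feat, n_shuf)
      xp <- x
      xp[, idx] <- xp[sample.int(nrow(x)), idx, drop = FALSE]
      pp <- prcomp(xp, center = TRUE, scale. = FALSE, rank. = n_components)
      null_load[[b]] <- abs(pp$rotation[idx, , drop = FALSE])
    }
    null_mat <- do.call(rbind, null_load)   # pooled null |loadings|
    comp_p <- vapply(seq_len(n_components), function(cmp) {
      nl <- sort(null_mat[, cmp])
      ## per-feature empirical p of observed |loading| vs pooled null
      pf <- 1 - (findInterval(abs(obs_load[, cmp]), nl) / (length(nl) + 1))
      suppressWarnings(
        ks.test(pf, "punif", alternative = "greater")$p.value)
    }, numeric(1))
  })
  list(scores = pc$x, loadings = obs_load, component_pvalues = comp_p,
       significant_components = which(comp_p < alpha))
}

#' Louvain clustering on a shared-nearest-neighbor graph
#'
#' Builds a k-nearest-neighbor graph on the sample scores (Euclidean),
#' converts it to shared-nearest-neighbor weights (Jaccard similarity of
#' neighbor sets, pruned below 1/15) and partitions it with Louvain
#' modularity at the given resolution. Singleton communities are merged into
#' the nearest cluster by centroid distance.
#'
#' @param scores samples x components numeric matrix (e.g. the significant
#'   components of [jackstraw()])
#' @param k_neighbors neighborhood size (includes the sample itself)
#' @param resolution Louvain resolution; larger values give more clusters
#' @param prune SNN weights below this are dropped
#' @param seed integer RNG seed
#' @return list with \code{labels} (named integers from 0),
#'   \code{resolution}, \code{k_neighbors}, \code{seed}
#' @export
snnCluster <- function(scores, k_neighbors = 20, resolution = 0.6,
                       prune = 1 / 15, seed = 1) {
  x <- as.matrix(scores)
  n <- nrow(x)
  if (k_neighbors >= n) stop("k_neighbors must be smaller than the sample count")
  dmat <- as.matrix(dist(x))
  ## neighbor sets include the sample itself, so duplicates share k neighbors
  nbr <- matrix(FALSE, n, n)
  for (i in seq_len(n))
    nbr[i, order(dmat[i, ])[seq_len(k_neighbors)]] <- TRUE
  shared <- tcrossprod(nbr * 1)
  jac <- shared / (2 * k_neighbors - shared)
  jac[jac < prune] <- 0
  diag(jac) <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "max", weighted = TRUE)
  comm <- withSeed(seed,
    igraph::cluster_louvain(g, resolution = resolution))
  lab <- igraph::membership(comm)
  ## merge singleton communities into the nearest cluster by centroid
  tabs <- table(lab)
  singles <- as.integer(names(tabs)[tabs == 1])
  if (length(singles) && length(tabs) > length(singles)) {
    for (cl in singles) {
      i <- which(lab == cl)
      others <- setdiff(unique(lab), c(singles))
      cent <- vapply(others, function(o)
        sqrt(sum((colMeans(x[lab == o, , drop = FALSE]) - x[i, ])^2)),
        numeric(1))
      lab[i] <- others[which.min(cent)]
    }
    message(length(singles), " singleton(s) merged into nearest cluster")
  }
  lab <- as.integer(factor(lab)) - 1L
  names(lab) <- rownames(x)
  list(labels = lab, resolution = resolution, k_neighbors = k_neighbors,
       seed = seed)
}
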