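## Missing-value handling preceding differential expression: features missing
## in over half the samples are dropped; the remainder are completed by a
## three-method ensemble imputation (kNN on feature profiles, row mean,
## iterative low-rank SVD).

#' Drop features with excessive missingness
#'
#' A feature is removed when its missing fraction strictly exceeds
#' \code{max_missing_frac} ("over 50\%" at the default); survivors keep
#' their original order.
#'
#' @param matrix an \linkS4class{AbundanceExperiment}
#' @param max_missing_frac tolerated missing fraction, default 0.5
#' @return the filtered \linkS4class{AbundanceExperiment}; the removed
#'   feature ids are attached as attribute \code{"removed"} and reported via
#'   \code{message}.
#' @export
filterMissing <- function(matrix, max_missing_frac = 0.5) {
  m <- abundance(matrix)
  if (!nrow(m)) stop("empty matrix")
  frac <- rowMeans(is.na(m))
  drop <- frac > max_missing_frac
  if (all(drop))
    stop("all features exceed the missing-fraction threshold (",
         max_missing_frac, "); lower the threshold or check the input")
  if (any(drop))
    message(sum(drop), " features removed for missingness > ",
            max_missing_frac)
  out <- AbundanceExperiment(m[!drop, , drop = FALSE], sampleDesign(matrix))
  attr(out, "removed") <- rownames(m)[drop]
  out
}

#' Impute remaining missing abundances
#'
#' Completes a filtered abundance matrix. The default \code{ensemble} is the
#' elementwise mean of three imputations: kNN over feature profiles
#' (Euclidean distance on shared observed samples, mean of the k nearest
#' observed neighbors), the feature mean, and an iterative rank-r SVD fit
#' (missing cells repeatedly replaced by their low-rank reconstruction).
#' Observed cells are never altered; an already-complete matrix is returned
#' unchanged for every method.
#'
#' @param matrix an \linkS4class{AbundanceExperiment}; run [filterMissing()]
#'   first so every feature is at least half observed
#' @param method one of \code{"ensemble"}, \code{"knn"}, \code{"row_mean"},
#'   \code{"svd_iterative"}
#' @param k neighbors for kNN (must be < number of features)
#' @param rank target rank of the SVD fit
#' @param maxit,tol SVD iteration controls
#' @return a complete \linkS4class{AbundanceExperiment}
#' @export
imputeAbundance <- function(matrix,
                            method = c("ensemble", "knn", "row_mean",
                                       "svd_iterative"),
                            k = 10, rank = 5, maxit = 50, tol = 1e-4) {
  method <- match.arg(method)
  m <- abundance(matrix)
  if (!anyNA(m)) return(matrix)
  if (k >= nrow(m)) stop("k must be smaller than the number of features")
  filled <- switch(method,
    row_mean = .imputeRowMean(m),
    knn = .imputeKnn(m, k),
    svd_iterative = .imputeSvd(m, rank, maxit, tol),
    ensemble = {
      stack <- (.imputeKnn(m, k) + .imputeRowMean(m) +
                  .imputeSvd(m, rank, maxit, tol)) / 3
      stack
    })
  filled[!is.na(m)] <- m[!is.na(m)]   # observed cells are inviolate
  AbundanceExperiment(filled, sampleDesign(matrix))
}

.imputeRowMean <- function(m) {
  rm_ <- rowMeans(m, na.rm = TRUE)
  rm_[!is.finite(rm_)] <- 0
  out <- m
  idx <- which(is.na(m), arr.ind = TRUE)
  out[idx] <- rm_[idx[, 1]]
  out
}

.imputeKnn <- function(m, k) {
  obs <- !is.na(m)
  a <- m; a[!obs] <- 0
  o <- obs * 1
  x2 <- a^2
  ## squared Euclidean distance restricted to shared observed samples,
  ## normalized to a mean squared difference
  cross <- tcrossprod(a)
  s1 <- x2 %*% t(o)
  n_shared <- tcrossprod(o)
  d2 <- s1 + t(s1) - 2 * cross
  msd <- d2 / n_shared
  msd[n_shared == 0] <- Inf
  diag(msd) <- Inf
  out <- m
  rowmean <- rowMeans(m, na.rm = TRUE)
  for (i in which(rowSums(!obs) > 0)) {
    ord <- order(msd[i, ])
    for (s in which(!obs[i, ])) {
      nb <- ord[obs[ord, s]]
      nb <- nb[is.finite(msd[i, nb])]
      out[i, s] <- if (length(nb)) mean(m[head(nb, k), s]) else rowmean[i]
    }
  }
  out
}

.imputeSvd <- function(m, rank, maxit, tol) {
  miss <- is.na(m)
  cur <- .imputeRowMean(m)
  r <- min(rank, dim(m) - 1L)
  for (it in seq_len(maxit)) {
    sv <- svd(cur, nu = r, nv = r)
    rec <- sv$u %*% (sv$d[seq_len(r)] * t(sv$v))
    delta <- sqrt(mean((rec[miss] - cur[miss])^2))
    cur[miss] <- rec[miss]
    if (delta < tol) break
  }
  cur
}
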