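## Pan-cancer regulatory atlas: per-cohort up/down tallies of E3s and DUBs,
## the signed column-scaled log2FC matrix behind the heatmap, Ward row
## clustering, and hypergeometric over-representation of gene sets per
## cluster.

#' Tally up/down regulation of catalog enzymes per cohort
#'
#' Counts catalog members with strictly positive (up) or strictly negative
#' (down) log2FC in each cohort's differential-expression table; zero
#' fold changes count in neither direction.
#'
#' @param tables named list of [testDifferential()] tables, one per cohort
#' @param catalog an \linkS4class{EnzymeCatalog}
#' @return data.frame with columns cohort, e3_up, e3_down, dub_up, dub_down
#' @export
tallyRegulation <- function(tables, catalog) {
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    stop("tables must be a named list keyed by cohort")
  count <- function(de, set, dir) {
    de <- de[de$feature_id %in% set, , drop = FALSE]
    if (dir > 0) sum(de$log2FC > 0, na.rm = TRUE)
    else sum(de$log2FC < 0, na.rm = TRUE)
  }
  do.call(rbind, lapply(names(tables), function(co) {
    de <- tables[[co]]
    data.frame(cohort = co,
               e3_up = count(de, e3Symbols(catalog), 1),
               e3_down = count(de, e3Symbols(catalog), -1),
               dub_up = count(de, dubSymbols(catalog), 1),
               dub_down = count(de, dubSymbols(catalog), -1),
               stringsAsFactors = FALSE)
  }))
}

#' Signed per-column scaling of a log2FC matrix
#'
#' Within each column (cohort), positive entries are divided by the column's
#' maximum positive value and negative entries by the magnitude of the
#' column's minimum, mapping the column into \[-1, 1\] while preserving the
#' sign structure. Zeros stay zero and missing entries stay missing.
#'
#' @param log2fc numeric matrix, enzymes x cohorts, NA allowed
#' @return the scaled matrix (same dimnames)
#' @export
signedColumnScale <- function(log2fc) {
  m <- as.matrix(log2fc)
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    if (all(is.na(v))) stop("column ", j, " is entirely missing")
    pos <- which(!is.na(v) & v > 0)
    neg <- which(!is.na(v) & v < 0)
    if (length(pos)) m[pos, j] <- v[pos] / max(v[pos])
    if (length(neg)) m[neg, j] <- v[neg] / abs(min(v[neg]))
  }
  m
}

#' Ward clustering of atlas rows
#'
#' Agglomerative clustering with the ward.D2 convention (Euclidean
#' distances, not pre-squared). Missing cells enter the distance computation
#' as 0 (the scaled matrix's neutral point) but are not otherwise modified.
#'
#' @param matrix numeric matrix (e.g. from [signedColumnScale()])
#' @param k_rows number of row clusters to cut
#' @return list with \code{labels} (named integer vector), \code{order}
#'   (dendrogram leaf order) and \code{heights} (merge heights)
#' @export
wardCluster <- function(matrix, k_rows = 3) {
  m <- as.matrix(matrix)
  if (k_rows < 2) stop("k_rows must be >= 2")
  if (k_rows > nrow(m)) stop("k_rows exceeds the number of rows")
  m0 <- m; m0[is.na(m0)] <- 0
  hc <- hclust(dist(m0), method = "ward.D2")
  list(labels = cutree(hc, k = k_rows), order = hc$order,
       heights = hc$height)
}

#' Hypergeometric over-representation of gene sets
#'
#' For each set, p is the upper tail P\[X >= overlap\] of the hypergeometric
#' distribution induced by drawing \code{length(query)} genes from the
#' universe; sets with zero overlap get p = 1 by convention. q-values are BH
#' across the collection.
#'
#' @param query character, the gene list of interest (subset of universe)
#' @param universe character, the background gene list
#' @param sets a \linkS4class{GeneSetCollection}; members are intersected
#'   with the universe
#' @return data.frame with columns set_id, overlap, set_size, universe_size,
#'   n_query, p, q, members
#' @export
oraEnrich <- function(query, universe, sets) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  query <- unique(query)
  if (length(setdiff(query, universe)))
    stop("query must be a subset of the universe")
  ids <- names(geneSets(sets))
  rows <- lapply(ids, function(id) {
    mem <- intersect(geneSets(sets)[[id]], universe)
    ov <- intersect(mem, query)
    p <- if (length(ov) == 0) 1 else
      phyper(length(ov) - 1, length(mem),
             length(universe) - length(mem), length(query),
             lower.tail = FALSE)
    data.frame(set_id = id, overlap = length(ov), set_size = length(mem),
               universe_size = length(universe), n_query = length(query),
               p = p, members = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bhAdjust(out$p)
  out[c("set_id", "overlap", "set_size", "universe_size", "n_query",
        "p", "q", "members")]
}
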