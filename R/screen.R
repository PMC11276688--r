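## The multi-omics degradative-ubiquitination screen. An E3-substrate pair
## is called over-ubiquitinated when (a) the substrate has an up-regulated
## ubiquitination site and (b) the E3's protein is up-regulated; it is
## called degradative when additionally (c) the substrate's protein drops
## without a matching mRNA drop, or its protein is flat while its mRNA
## rises — the signature of excess proteasomal degradation.

#' Screening thresholds
#'
#' Defaults follow the reference screen: site log2FC > 0 at q < 0.05;
#' E3 log2FC >= 0.5 at q < 0.01; substrate protein and mRNA tested at
#' q < 0.01. All q bounds are strict upper bounds; the E3 fold-change bound
#' is the one non-strict inequality.
#'
#' @param site_fc_min exclusive lower bound on site log2FC
#' @param site_q_max strict upper bound on site q
#' @param e3_fc_min inclusive lower bound on E3 log2FC
#' @param e3_q_max strict upper bound on E3 q
#' @param prot_q_max strict upper bound on substrate protein q
#' @param rna_q_max strict upper bound on substrate mRNA q
#' @return list of class \code{ScreenThresholds}
#' @export
screenThresholds <- function(site_fc_min = 0, site_q_max = 0.05,
                             e3_fc_min = 0.5, e3_q_max = 0.01,
                             prot_q_max = 0.01, rna_q_max = 0.01) {
  th <- list(site_fc_min = site_fc_min, site_q_max = site_q_max,
             e3_fc_min = e3_fc_min, e3_q_max = e3_q_max,
             prot_q_max = prot_q_max, rna_q_max = rna_q_max)
  qs <- c(site_q_max, e3_q_max, prot_q_max, rna_q_max)
  if (any(qs <= 0 | qs > 1)) stop("q thresholds must lie in (0, 1]")
  class(th) <- "ScreenThresholds"
  th
}

#' Significantly differentially expressed E3s
#'
#' Catalog E3s with q < 0.01 and |log2FC| strictly greater than 0.5 (the
#' definition of significance for enzymes; note the screen's criterion (b)
#' separately uses a non-strict >= 0.5).
#'
#' @param prot_de a [testDifferential()] table
#' @param catalog an \linkS4class{EnzymeCatalog}
#' @param fc_min strict fold-change bound
#' @param q_max strict q bound
#' @return list with character vectors \code{up} and \code{down}
#' @export
selectSignificantE3 <- function(prot_de, catalog, fc_min = 0.5,
                                q_max = 0.01) {
  de <- prot_de[prot_de$feature_id %in% e3Symbols(catalog), , drop = FALSE]
  sig <- !is.na(de$q) & de$q < q_max & abs(de$log2FC) > fc_min
  list(up = de$feature_id[sig & de$log2FC > 0],
       down = de$feature_id[sig & de$log2FC < 0])
}

#' Classify one E3-substrate pair
#'
#' Applies the three screening criteria to the pair's statistics. Site rows
#' are the substrate's ubiquitination sites; any single passing site
#' satisfies criterion (a). "Not significantly down-regulated" mRNA means
#' the negation of (log2FC < 0 and q < rna_q_max); "no significant protein
#' change" means protein q >= prot_q_max.
#'
#' @param site_rows data.frame of the substrate's site statistics (columns
#'   feature_id, log2FC, q); NULL or empty when unmeasured
#' @param e3_row one-row data.frame of the E3's protein statistics
#' @param prot_row one-row data.frame of the substrate's protein statistics
#' @param rna_row one-row data.frame of the substrate's mRNA statistics
#' @param thresholds a [screenThresholds()]
#' @return one-row data.frame with call (\code{degradative} /
#'   \code{over_ubiquitinated} / \code{none} / \code{skipped}), branch,
#'   evidence columns and a reason code for skips
#' @export
classifyESI <- function(site_rows, e3_row, prot_row, rna_row,
                        thresholds = screenThresholds()) {
  th <- thresholds
  skip <- function(reason) data.frame(
    call = "skipped", branch = "none", sites_passing = "",
    site_log2FC = NA_real_, site_q = NA_real_, e3_log2FC = NA_real_,
    e3_q = NA_real_, prot_log2FC = NA_real_, prot_q = NA_real_,
    rna_log2FC = NA_real_, rna_q = NA_real_, reason = reason,
    stringsAsFactors = FALSE)
  if (is.null(site_rows) || !nrow(site_rows)) return(skip("no_sites"))
  if (is.null(e3_row) || !nrow(e3_row)) return(skip("no_e3_protein"))
  if (is.null(prot_row) || !nrow(prot_row)) return(skip("no_substrate_protein"))
  if (is.null(rna_row) || !nrow(rna_row)) return(skip("no_substrate_rna"))
  ok <- !is.na(site_rows$q)
  pass_a <- ok & site_rows$log2FC > th$site_fc_min &
    site_rows$q < th$site_q_max
  a <- any(pass_a)
  best <- if (a) which(pass_a)[which.min(site_rows$q[pass_a])] else
    which.min(site_rows$q)
  if (!length(best) || all(is.na(site_rows$q))) best <- 1L
  b <- !is.na(e3_row$q) && e3_row$log2FC >= th$e3_fc_min &&
    e3_row$q < th$e3_q_max
  rna_down <- !is.na(rna_row$q) && rna_row$log2FC < 0 &&
    rna_row$q < th$rna_q_max
  branch1 <- !is.na(prot_row$q) && prot_row$log2FC < 0 &&
    prot_row$q < th$prot_q_max && !rna_down
  branch2 <- !is.na(prot_row$q) && prot_row$q >= th$prot_q_max &&
    !is.na(rna_row$q) && rna_row$log2FC > 0 && rna_row$q < th$rna_q_max
  over <- a && b
  degr <- over && (branch1 || branch2)
  data.frame(
    call = if (degr) "degradative" else if (over) "over_ubiquitinated"
           else "none",
    branch = if (!degr) "none" else if (branch1)
      "protein_down_mrna_not_down" else "protein_flat_mrna_up",
    sites_passing = paste(site_rows$feature_id[pass_a], collapse = ","),
    site_log2FC = site_rows$log2FC[best], site_q = site_rows$q[best],
    e3_log2FC = e3_row$log2FC, e3_q = e3_row$q,
    prot_log2FC = prot_row$log2FC, prot_q = prot_row$q,
    rna_log2FC = rna_row$log2FC, rna_q = rna_row$q,
    reason = "", stringsAsFactors = FALSE)
}

#' Run the degradative-ubiquitination screen over an ESI network
#'
#' Evaluates every E3-substrate edge against the site, protein and mRNA
#' differential-expression tables and summarizes the distinct enzymes and
#' substrates at each call level. The full evidence behind each call is kept
#' as an audit trail.
#'
#' @param esi an \linkS4class{ESINetwork}
#' @param site_de a [testSites()] table (needs a \code{parent} column or
#'   site ids in \code{GENE_K123} form)
#' @param prot_de,rna_de [testDifferential()] / [testRNA()] tables on the
#'   same cohort
#' @param thresholds a [screenThresholds()]
#' @return list with \code{calls} (one row per edge) and \code{summary}
#'   (data.frame of distinct E3/substrate counts per call level)
#' @export
runScreen <- function(esi, site_de, prot_de, rna_de,
                      thresholds = screenThresholds()) {
  edges <- esiEdges(esi)
  if (!nrow(edges)) stop("empty ESI network")
  for (nm in c("site_de", "prot_de", "rna_de")) {
    tab <- get(nm)
    if (is.null(tab) || !is.data.frame(tab))
      stop("missing differential-expression layer: ", nm)
  }
  if (!"parent" %in% colnames(site_de))
    site_de$parent <- siteParent(site_de$feature_id)
  site_by_parent <- split(site_de, site_de$parent)
  prot_idx <- setNames(seq_len(nrow(prot_de)), prot_de$feature_id)
  rna_idx <- setNames(seq_len(nrow(rna_de)), rna_de$feature_id)
  rows <- lapply(seq_len(nrow(edges)), function(i) {
    e3 <- edges$e3[i]; sub <- edges$substrate[i]
    cl <- classifyESI(
      site_rows = site_by_parent[[sub]],
      e3_row = if (e3 %in% names(prot_idx))
        prot_de[prot_idx[[e3]], , drop = FALSE] else NULL,
      prot_row = if (sub %in% names(prot_idx))
        prot_de[prot_idx[[sub]], , drop = FALSE] else NULL,
      rna_row = if (sub %in% names(rna_idx))
        rna_de[rna_idx[[sub]], , drop = FALSE] else NULL,
      thresholds = thresholds)
    cbind(data.frame(e3 = e3, substrate = sub, stringsAsFactors = FALSE), cl)
  })
  calls <- do.call(rbind, rows)
  lvl <- function(keep) data.frame(
    n_pairs = sum(keep), n_e3 = length(unique(calls$e3[keep])),
    n_substrates = length(unique(calls$substrate[keep])))
  summary <- cbind(
    call = c("over_ubiquitinated", "degradative"),
    rbind(lvl(calls$call %in% c("over_ubiquitinated", "degradative")),
          lvl(calls$call == "degradative")))
  list(calls = calls, summary = summary)
}
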