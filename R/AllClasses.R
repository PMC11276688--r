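#' @import methods
#' @importFrom stats median sd mad cor quantile rnorm rbinom rnbinom rexp runif
#'   wilcox.test p.adjust phyper ks.test prcomp hclust cutree dist cor.test
#'   setNames complete.cases pchisq qnorm var coef
#' @importFrom utils head read.delim write.table
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Abundance matrix with sample design
#'
#' The central container of the package: a features x samples matrix of
#' log-ratio abundances (proteome, protein-corrected ubiquitination sites, or
#' normalized RNA) stored as a \linkS4class{SummarizedExperiment} whose
#' \code{colData} carries the sample design (\code{cohort}, \code{condition}
#' in \code{tumor}/\code{normal}, optional \code{pair_id} linking a tumor
#' sample to its normal adjacent tissue). Missing abundances are \code{NA}.
#'
#' @slot .. inherits all slots from \code{SummarizedExperiment}; the single
#'   assay is named \code{"abundance"}.
#' @seealso [AbundanceExperiment()] for construction from a matrix and a
#'   design data.frame, [readAbundanceMatrix()] for construction from TSV.
#' @exportClass AbundanceExperiment
setClass("AbundanceExperiment", contains = "SummarizedExperiment")

setValidity("AbundanceExperiment", function(object) {
  msg <- character()
  if (!"abundance" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'abundance' is required")
  fid <- rownames(object); sid <- colnames(object)
  if (is.null(fid) || anyDuplicated(fid))
    msg <- c(msg, "feature ids must be present and unique")
  if (is.null(sid) || anyDuplicated(sid))
    msg <- c(msg, "sample ids must be present and unique")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("cohort", "condition") %in% colnames(cd))) {
    msg <- c(msg, "design must provide 'cohort' and 'condition'")
  } else if (!all(cd$condition %in% c("tumor", "normal"))) {
    msg <- c(msg, "condition must be 'tumor' or 'normal'")
  }
  if ("pair_id" %in% colnames(cd)) {
    pid <- cd$pair_id
    keep <- !is.na(pid) & pid != ""
    if (any(keep)) {
      tab <- table(pid[keep], cd$condition[keep])
      if (any(tab > 1))
        msg <- c(msg, "each pair_id may map to at most one tumor and one normal sample")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AbundanceExperiment
#'
#' @param values numeric matrix, features x samples, with rownames (feature
#'   ids) and colnames (sample ids); \code{NA} marks missing abundances.
#' @param design data.frame with columns \code{sample_id}, \code{cohort},
#'   \code{condition} (\code{"tumor"}/\code{"normal"}) and optionally
#'   \code{pair_id}; must cover every column of \code{values}.
#' @return An \linkS4class{AbundanceExperiment}.
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("P", 1:3), c("s1", "s2")))
#' d <- data.frame(sample_id = c("s1", "s2"), cohort = "LSCC",
#'                 condition = c("tumor", "normal"), pair_id = "pt1")
#' AbundanceExperiment(m, d)
#' @export
AbundanceExperiment <- function(values, design) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("'values' must be numeric")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' needs feature ids as rownames and sample ids as colnames")
  design <- as.data.frame(design)
  if (!"sample_id" %in% colnames(design)) stop("design requires a 'sample_id' column")
  if (anyDuplicated(design$sample_id)) stop("duplicate sample_id in design")
  orphan <- setdiff(colnames(values), design$sample_id)
  if (length(orphan))
    stop("samples absent from design: ", paste(orphan, collapse = ", "))
  design <- design[match(colnames(values), design$sample_id), , drop = FALSE]
  if (!"pair_id" %in% colnames(design)) design$pair_id <- NA_character_
  design$pair_id[design$pair_id %in% ""] <- NA_character_
  cd <- S4Vectors::DataFrame(design[setdiff(colnames(design), "sample_id")],
                             row.names = design$sample_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = values), colData = cd)
  new("AbundanceExperiment", se)
}

#' @describeIn AbundanceExperiment extract the abundance matrix.
#' @param x an AbundanceExperiment
#' @export
abundance <- function(x) SummarizedExperiment::assay(x, "abundance")

#' @describeIn AbundanceExperiment sample design as a plain data.frame with a
#'   \code{sample_id} column.
#' @export
sampleDesign <- function(x) {
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  cbind(sample_id = colnames(x), cd, stringsAsFactors = FALSE)
}

#' Complete tumor/normal pairs of a paired design
#'
#' @param x an AbundanceExperiment with pair ids
#' @return data.frame with columns \code{pair_id}, \code{tumor},
#'   \code{normal} (sample ids), one row per pair observed in both arms.
#' @export
completePairs <- function(x) {
  d <- sampleDesign(x)
  d <- d[!is.na(d$pair_id), , drop = FALSE]
  tum <- d[d$condition == "tumor", c("pair_id", "sample_id")]
  nor <- d[d$condition == "normal", c("pair_id", "sample_id")]
  m <- merge(tum, nor, by = "pair_id", suffixes = c("_t", "_n"))
  data.frame(pair_id = m$pair_id, tumor = m$sample_id_t,
             normal = m$sample_id_n, stringsAsFactors = FALSE)
}

setMethod("show", "AbundanceExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("AbundanceExperiment:", nrow(object), "features x", ncol(object),
      "samples\n")
  cat("  cohorts:", paste(unique(cd$cohort), collapse = ", "), "\n")
  cat("  tumor:", sum(cd$condition == "tumor"),
      " normal:", sum(cd$condition == "normal"),
      " paired:", nrow(completePairs(object)), "\n")
  cat("  missing:", sprintf("%.1f%%", 100 * mean(is.na(abundance(object)))),
      "\n")
})

#' Catalog of ubiquitination enzymes
#'
#' Gene symbols of E3 ubiquitin ligases and deubiquitinases (DUBs). The two
#' sets may only overlap when \code{allowOverlap} is set, since a symbol
#' annotated with both activities is usually a curation error.
#'
#' @slot e3 character, E3 ligase symbols
#' @slot dub character, deubiquitinase symbols
#' @slot allowOverlap logical flag permitting shared symbols
#' @export EnzymeCatalog
#' @exportClass EnzymeCatalog
EnzymeCatalog <- setClass("EnzymeCatalog",
  representation(e3 = "character", dub = "character",
                 allowOverlap = "logical"),
  prototype(allowOverlap = FALSE))

setValidity("EnzymeCatalog", function(object) {
  msg <- character()
  if (length(object@e3) == 0 && length(object@dub) == 0)
    msg <- c(msg, "catalog must not be empty")
  if (anyDuplicated(object@e3) || anyDuplicated(object@dub))
    msg <- c(msg, "duplicate symbols within a catalog set")
  if (!object@allowOverlap && length(intersect(object@e3, object@dub)))
    msg <- c(msg, "e3 and dub sets intersect; set allowOverlap = TRUE to permit")
  if (length(msg)) msg else TRUE
})

#' @describeIn EnzymeCatalog E3 symbols
#' @param x an EnzymeCatalog
#' @export
e3Symbols <- function(x) x@e3

#' @describeIn EnzymeCatalog DUB symbols
#' @export
dubSymbols <- function(x) x@dub

setMethod("show", "EnzymeCatalog", function(object) {
  cat("EnzymeCatalog:", length(object@e3), "E3,", length(object@dub),
      "DUBs\n")
})

#' Directed E3-substrate interaction network
#'
#' Experimentally supported E3 -> substrate edges, unique by
#' (e3, substrate); the \code{source} column records provenance.
#'
#' @slot edges data.frame with character columns e3, substrate, source
#' @slot allowSelf logical, whether autoubiquitination edges are permitted
#' @export ESINetwork
#' @exportClass ESINetwork
ESINetwork <- setClass("ESINetwork",
  representation(edges = "data.frame", allowSelf = "logical"),
  prototype(edges = data.frame(e3 = character(), substrate = character(),
                               source = character()),
            allowSelf = FALSE))

setValidity("ESINetwork", function(object) {
  e <- object@edges
  msg <- character()
  if (!all(c("e3", "substrate") %in% colnames(e)))
    msg <- c(msg, "edges need columns 'e3' and 'substrate'")
  else {
    if (anyDuplicated(e[c("e3", "substrate")]))
      msg <- c(msg, "duplicate (e3, substrate) edges")
    if (!object@allowSelf && any(e$e3 == e$substrate))
      msg <- c(msg, "self-edges present; set allowSelf = TRUE to permit")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ESINetwork edge list as a data.frame
#' @param x an ESINetwork
#' @export
esiEdges <- function(x) x@edges

#' @describeIn ESINetwork known substrates of one E3
#' @param e3 a gene symbol
#' @export
substratesOf <- function(x, e3) unique(x@edges$substrate[x@edges$e3 == e3])

setMethod("show", "ESINetwork", function(object) {
  cat("ESINetwork:", nrow(object@edges), "edges,",
      length(unique(object@edges$e3)), "E3,",
      length(unique(object@edges$substrate)), "substrates\n")
})

#' Collection of gene sets
#'
#' Named gene sets (e.g. KEGG pathways read from GMT) used for
#' over-representation analysis.
#'
#' @slot sets named list of character vectors (members, deduplicated)
#' @slot descriptions character, one per set
#' @export GeneSetCollection
#' @exportClass GeneSetCollection
GeneSetCollection <- setClass("GeneSetCollection",
  representation(sets = "list", descriptions = "character"))

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  if (length(object@sets)) {
    if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
      msg <- c(msg, "set ids must be unique and named")
    if (any(lengths(object@sets) == 0))
      msg <- c(msg, "sets must have at least one member")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn GeneSetCollection member lists
#' @param x a GeneSetCollection
#' @export
geneSets <- function(x) x@sets

setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection:", length(object@sets), "sets; sizes",
      if (length(object@sets)) paste(range(lengths(object@sets)),
                                     collapse = "-") else "-", "\n")
})

setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' Signed pathway topology
#'
#' One signaling pathway as a node set plus signed directed edges
#' (+1 activation, -1 inhibition), the input of the pathway impact engine.
#'
#' @slot pathwayId character scalar
#' @slot nodes character, all pathway members (isolated nodes allowed)
#' @slot edges data.frame with columns source, target, sign (+/-1), relation
#' @export PathwayGraph
#' @exportClass PathwayGraph
PathwayGraph <- setClass("PathwayGraph",
  representation(pathwayId = "character", nodes = "character",
                 edges = "data.frame"))

setValidity("PathwayGraph", function(object) {
  e <- object@edges
  msg <- character()
  if (length(object@pathwayId) != 1) msg <- c(msg, "pathwayId must be scalar")
  if (anyDuplicated(object@nodes)) msg <- c(msg, "duplicate nodes")
  if (nrow(e)) {
    if (!all(c("source", "target", "sign") %in% colnames(e)))
      msg <- c(msg, "edges need columns source, target, sign")
    else {
      if (!all(e$sign %in% c(-1, 1))) msg <- c(msg, "edge signs must be +/-1")
      if (!all(c(e$source, e$target) %in% object@nodes))
        msg <- c(msg, "edge endpoints must be pathway nodes")
    }
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn PathwayGraph node symbols
#' @param x a PathwayGraph
#' @export
pathwayNodes <- function(x) x@nodes

#' @describeIn PathwayGraph signed edge list
#' @export
pathwayEdges <- function(x) x@edges

#' @describeIn PathwayGraph pathway identifier
#' @export
pathwayId <- function(x) x@pathwayId

setMethod("show", "PathwayGraph", function(object) {
  cat("PathwayGraph", object@pathwayId, ":", length(object@nodes), "nodes,",
      nrow(object@edges), "signed edges\n")
})

#' Validate a survival table
#'
#' Time-to-event records with a continuous marker, as consumed by the
#' prognosis functions. Kept as a plain data.frame (the convention of the
#' survival package) behind a validating constructor.
#'
#' @param df data.frame with columns \code{sample_id}, \code{time}
#'   (nonnegative), \code{event} (0/1) and \code{marker} (numeric)
#' @return the validated data.frame
#' @export
survivalTable <- function(df) {
  df <- as.data.frame(df)
  need <- c("sample_id", "time", "event", "marker")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("survival table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (any(df$time < 0)) stop("survival times must be nonnegative")
  if (!all(df$event %in% c(0, 1))) stop("events must be 0/1")
  df
}
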