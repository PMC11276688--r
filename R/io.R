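## Readers/writers for the package's plain-text interchange formats. All
## tables are TSV; missing abundances are an empty cell or "NA" on read and
## written back as "NA" (the common proteomics dialects).

#' Read an abundance matrix with its sample design
#'
#' @param path TSV: header row of sample ids, first column feature ids,
#'   numeric cells; empty cells or \code{NA} mark missing abundances.
#' @param design_path TSV with columns \code{sample_id}, \code{cohort},
#'   \code{condition}, and optionally \code{pair_id} (empty allowed).
#' @return An \linkS4class{AbundanceExperiment}.
#' @export
readAbundanceMatrix <- function(path, design_path) {
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", na.strings = NULL)
  if (ncol(raw) < 2) stop("abundance TSV needs a feature column and >= 1 sample")
  fid <- raw[[1]]
  if (anyDuplicated(fid)) stop("duplicate feature ids in ", path)
  sid <- colnames(raw)[-1]
  if (anyDuplicated(sid)) stop("duplicate sample ids in ", path)
  vals <- matrix(NA_real_, nrow(raw), length(sid),
                 dimnames = list(fid, sid))
  for (j in seq_along(sid)) {
    cell <- raw[[j + 1]]
    missing <- is.na(cell) | cell == "" | cell == "NA"
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!missing & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric cell '%s' at feature '%s', sample '%s'",
                   cell[bad[1]], fid[bad[1]], sid[j]))
    num[missing] <- NA_real_
    vals[, j] <- num
  }
  design <- read.delim(design_path, header = TRUE, sep = "\t",
                       check.names = FALSE, colClasses = "character")
  AbundanceExperiment(vals, design)
}

#' Write an abundance matrix (and optionally its design) to TSV
#'
#' Missing cells are written as \code{NA}; full numeric precision is kept so
#' a write-then-read round trip is value-identical.
#'
#' @param x an \linkS4class{AbundanceExperiment}
#' @param path output TSV for the matrix
#' @param design_path optional output TSV for the design
#' @export
writeAbundanceMatrix <- function(x, path, design_path = NULL) {
  m <- abundance(x)
  chr <- matrix(sprintf("%.17g", m), nrow(m), ncol(m),
                dimnames = dimnames(m))
  chr[is.na(m)] <- "NA"
  out <- data.frame(feature_id = rownames(m), chr, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(design_path))
    write.table(sampleDesign(x), design_path, sep = "\t", quote = FALSE,
                row.names = FALSE, na = "")
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path standard GMT: per line set_id, description, members...
#' @return a \linkS4class{GeneSetCollection}; duplicate members within a line
#'   are deduplicated.
#' @export
readGeneSets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(GeneSetCollection(sets = list(), descriptions = character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short))
    stop("GMT line ", short[1], " has fewer than 3 fields")
  ids <- vapply(fields, `[[`, "", 1)
  if (anyDuplicated(ids)) stop("duplicate set ids in GMT")
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- ids
  GeneSetCollection(sets = sets,
                    descriptions = setNames(vapply(fields, `[[`, "", 2), ids))
}

#' Read signed pathway topologies from a TSV edge list
#'
#' @param path TSV with columns \code{pathway_id}, \code{source},
#'   \code{target}, \code{sign} (\code{1}/\code{-1}/\code{activation}/
#'   \code{inhibition}) and optionally \code{relation}.
#' @param node_path optional TSV sidecar (\code{pathway_id}, \code{node})
#'   declaring members, so isolated nodes can be represented.
#' @return list of \linkS4class{PathwayGraph}, one per pathway id.
#' @export
readPathwayGraphs <- function(path, node_path = NULL) {
  e <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character")
  need <- c("pathway_id", "source", "target", "sign")
  if (!all(need %in% colnames(e)))
    stop("pathway edge TSV needs columns: ", paste(need, collapse = ", "))
  sgn <- e$sign
  mapped <- ifelse(sgn %in% c("1", "+1", "activation"), 1,
                   ifelse(sgn %in% c("-1", "inhibition"), -1, NA))
  if (anyNA(mapped))
    stop("unrecognized edge sign '", sgn[which(is.na(mapped))[1]],
         "' (use +1/-1/activation/inhibition)")
  e$sign <- mapped
  if (!"relation" %in% colnames(e)) e$relation <- ifelse(mapped > 0,
                                                         "activation",
                                                         "inhibition")
  extra <- NULL
  if (!is.null(node_path)) {
    extra <- read.delim(node_path, header = TRUE, sep = "\t",
                        colClasses = "character")
  }
  lapply(split(e, e$pathway_id)[unique(e$pathway_id)], function(pe) {
    nodes <- unique(c(pe$source, pe$target))
    if (!is.null(extra))
      nodes <- unique(c(nodes, extra$node[extra$pathway_id == pe$pathway_id[1]]))
    PathwayGraph(pathwayId = pe$pathway_id[1], nodes = nodes,
                 edges = data.frame(source = pe$source, target = pe$target,
                                    sign = pe$sign, relation = pe$relation,
                                    stringsAsFactors = FALSE))
  })
}

#' Read an E3-substrate interaction network
#'
#' @param path TSV with columns \code{e3}, \code{substrate} and optionally
#'   \code{source}
#' @param allowSelf permit autoubiquitination edges
#' @return an \linkS4class{ESINetwork}
#' @export
readESINetwork <- function(path, allowSelf = FALSE) {
  e <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character")
  if (!all(c("e3", "substrate") %in% colnames(e)))
    stop("ESI TSV needs columns 'e3' and 'substrate'")
  if (!"source" %in% colnames(e)) e$source <- "unspecified"
  ESINetwork(edges = e[c("e3", "substrate", "source")], allowSelf = allowSelf)
}

#' Read an enzyme catalog from plain symbol lists
#'
#' @param e3_path,dub_path text files, one gene symbol per line
#' @param allowOverlap permit symbols annotated as both E3 and DUB
#' @return an \linkS4class{EnzymeCatalog}
#' @export
readEnzymeCatalog <- function(e3_path, dub_path, allowOverlap = FALSE) {
  rd <- function(p) unique(trimws(readLines(p))[nzchar(trimws(readLines(p)))])
  EnzymeCatalog(e3 = rd(e3_path), dub = rd(dub_path),
                allowOverlap = allowOverlap)
}

#' Read a survival table
#'
#' @param path TSV with columns sample_id, time, event, marker
#' @return validated data.frame (see [survivalTable()])
#' @export
readSurvivalTable <- function(path) {
  survivalTable(read.delim(path, header = TRUE, sep = "\t"))
}
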