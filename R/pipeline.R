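## End-to-end driver over the synthetic cohort: each analytic stage writes
## its tables to the output directory and a manifest records the seed,
## thresholds and stage list, so a rerun with the same configuration is
## byte-identical.

#' Build a small synthetic pathway collection
#'
#' Random signed topologies (chains with occasional branches) over fresh
#' node symbols, for exercising the pathway impact engine.
#'
#' @param n_pathways number of pathways
#' @param nodes_per nodes per pathway
#' @param node_symbols optional pool of symbols to draw nodes from (defaults
#'   to fresh \code{PWk_Nj} symbols)
#' @param seed integer RNG seed
#' @return list of \linkS4class{PathwayGraph}
#' @export
makeDemoPathways <- function(n_pathways = 5, nodes_per = 8,
                             node_symbols = NULL, seed = 1) {
  withSeed(seed, {
    lapply(seq_len(n_pathways), function(k) {
      nodes <- if (is.null(node_symbols))
        sprintf("PW%d_N%02d", k, seq_len(nodes_per))
      else sample(node_symbols, nodes_per)
      src <- nodes[seq_len(nodes_per - 1)]
      tgt <- nodes[-1]
      extra <- if (nodes_per > 4)
        data.frame(source = nodes[1], target = nodes[4],
                   sign = sample(c(-1, 1), 1), stringsAsFactors = FALSE)
      else NULL
      e <- rbind(data.frame(source = src, target = tgt,
                            sign = sample(c(-1, 1), nodes_per - 1,
                                          replace = TRUE, prob = c(.3, .7)),
                            stringsAsFactors = FALSE), extra)
      e$relation <- ifelse(e$sign > 0, "activation", "inhibition")
      e <- e[!duplicated(e[c("source", "target")]), ]
      PathwayGraph(pathwayId = sprintf("DEMO%02d", k), nodes = nodes,
                   edges = e)
    })
  })
}

#' Pipeline configuration
#'
#' Bundles the synthetic cohort specification, screening thresholds,
#' clustering resolutions and replication counts. The seed governs every
#' stochastic stage and is recorded in the output manifest.
#'
#' @param out_dir output directory (created if absent)
#' @param seed master integer seed
#' @param cohort a [cohortSpec()]
#' @param n_cohorts cohorts simulated for the cross-cancer stages
#' @param thresholds a [screenThresholds()]
#' @param resolution_tumor,resolution_normal SNN clustering resolutions
#' @param n_boot pPERT bootstrap replicates
#' @param n_perm maxstat permutation replicates
#' @param stages character subset of the analytic stages to run
#' @return list of class \code{PipelineConfig}
#' @export
pipelineConfig <- function(out_dir, seed = 1, cohort = cohortSpec(seed = seed),
                           n_cohorts = 3,
                           thresholds = screenThresholds(),
                           resolution_tumor = 0.6, resolution_normal = 0.5,
                           n_boot = 500, n_perm = 500,
                           stages = c("impute", "diffexp", "atlas",
                                      "cluster", "esi", "screen", "spia",
                                      "survival")) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), cohort = cohort,
              n_cohorts = n_cohorts, thresholds = thresholds,
              resolution_tumor = resolution_tumor,
              resolution_normal = resolution_normal,
              n_boot = n_boot, n_perm = n_perm, stages = stages)
  class(cfg) <- "PipelineConfig"
  cfg
}

.writeTsv <- function(df, dir, name) {
  write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
              row.names = FALSE)
}

#' Run the full synthetic analysis pipeline
#'
#' Simulates the configured cohorts and executes the requested analytic
#' stages, writing every table as TSV under \code{config$out_dir} along
#' with \code{manifest.json}. A custom \code{data} list (elements
#' \code{proteome}, \code{rna}, \code{sites}, \code{catalog}, \code{esi})
#' replaces the simulated first cohort, e.g. to run on real inputs.
#'
#' @param config a [pipelineConfig()]
#' @param data optional externally supplied first-cohort data
#' @return invisibly, the manifest list
#' @export
runPipeline <- function(config, data = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    if (!name %in% config$stages) return(NULL)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  relabel <- function(ae, co) {
    d <- sampleDesign(ae); d$cohort <- co
    d$sample_id <- paste0(co, "_", d$sample_id)
    m <- abundance(ae); colnames(m) <- d$sample_id
    d$pair_id <- ifelse(is.na(d$pair_id), NA_character_,
                        paste0(co, "_", d$pair_id))
    AbundanceExperiment(m, d)
  }
  ## cohort simulation (always runs; downstream stages consume it)
  cohorts <- lapply(seq_len(config$n_cohorts), function(k) {
    sp <- config$cohort; sp$seed <- config$seed + k
    sim <- simulateCohort(sp)
    for (nm in c("proteome", "rna", "sites"))
      sim[[nm]] <- relabel(sim[[nm]], sprintf("SYN%02d", k))
    sim
  })
  main <- cohorts[[1]]
  if (!is.null(data)) main <- modifyList(main, data)

  imputed <- stage("impute", {
    prot <- imputeAbundance(filterMissing(main$proteome))
    sites <- if (is.null(main$sites)) NULL else
      imputeAbundance(filterMissing(main$sites))
    .writeTsv(data.frame(feature_id = rownames(abundance(prot)),
                         round(abundance(prot), 6), check.names = FALSE),
              config$out_dir, "proteome_imputed.tsv")
    list(proteome = prot, sites = sites)
  })
  if (is.null(imputed))
    imputed <- list(proteome = main$proteome, sites = main$sites)

  de <- stage("diffexp", {
    prot_de <- lapply(seq_along(cohorts), function(k) {
      ae <- if (k == 1) imputed$proteome else
        suppressMessages(filterMissing(cohorts[[k]]$proteome))
      testDifferential(ae, paired = TRUE)
    })
    names(prot_de) <- sprintf("SYN%02d", seq_along(cohorts))
    rna_de <- testRNA(main$rna, paired = TRUE)
    sites_de <- if (is.null(imputed$sites))
      stop("missing ubiquitylome input") else testSites(imputed$sites)
    .writeTsv(prot_de[[1]], config$out_dir, "de_protein.tsv")
    .writeTsv(rna_de, config$out_dir, "de_rna.tsv")
    .writeTsv(sites_de, config$out_dir, "de_sites.tsv")
    list(prot = prot_de, rna = rna_de, sites = sites_de)
  })

  stage("atlas", {
    enz <- c(e3Symbols(main$catalog), dubSymbols(main$catalog))
    fc <- sapply(de$prot, function(t)
      t$log2FC[match(enz, t$feature_id)])
    rownames(fc) <- enz
    scaled <- signedColumnScale(fc)
    cl <- wardCluster(scaled, k_rows = min(3, nrow(scaled)))
    .writeTsv(data.frame(enzyme = rownames(scaled), round(scaled, 6),
                         cluster = cl$labels, check.names = FALSE),
              config$out_dir, "atlas_scaled.tsv")
    .writeTsv(tallyRegulation(de$prot, main$catalog), config$out_dir,
              "regulation_tally.tsv")
  })

  stage("cluster", {
    prots <- lapply(cohorts, function(co)
      suppressMessages(imputeAbundance(filterMissing(co$proteome))))
    z <- suppressMessages(zscoreByCohort(prots, "tumor"))
    feats <- intersectFeatures(prots, main$catalog, "e3")
    js <- jackstraw(z[feats, ], n_components = 10, perm_frac = 0.05,
                    n_perm = 30, seed = config$seed)
    comps <- if (length(js$significant_components))
      js$significant_components else 1:2
    cl <- snnCluster(js$scores[, comps, drop = FALSE], k_neighbors = 20,
                     resolution = config$resolution_tumor,
                     seed = config$seed)
    .writeTsv(data.frame(sample_id = names(cl$labels),
                         cluster = cl$labels),
              config$out_dir, "sample_clusters.tsv")
  })

  stage("esi", {
    ct <- pairwiseSpearman(imputed$proteome, main$esi, "tumor")
    cn <- pairwiseSpearman(imputed$proteome, main$esi, "normal")
    bg <- sampleRandomBackground(main$esi, imputed$proteome, main$esi,
                                 seed = config$seed)
    cb <- pairwiseSpearman(imputed$proteome, bg, "tumor",
                           is_substrate = FALSE)
    .writeTsv(rbind(ct, cn, cb), config$out_dir, "esi_correlations.tsv")
    .writeTsv(compareDistributions(ct, cn), config$out_dir,
              "esi_comparison.tsv")
  })

  screen <- stage("screen", {
    if (is.null(de)) stop("screen requires the diffexp stage")
    if (is.null(de$sites)) stop("missing ubiquitylome input")
    sc <- runScreen(main$esi, de$sites, de$prot[[1]], de$rna,
                    thresholds = config$thresholds)
    .writeTsv(sc$calls, config$out_dir, "screen_calls.tsv")
    .writeTsv(sc$summary, config$out_dir, "screen_summary.tsv")
    sc
  })

  stage("spia", {
    prot1 <- de$prot[[1]]
    sig <- prot1[!is.na(prot1$q) & prot1$q < 0.05 &
                   abs(prot1$log2FC) > 0.5, ]
    pw <- makeDemoPathways(5, 8, node_symbols = prot1$feature_id,
                           seed = config$seed)
    res <- runSPIA(data.frame(symbol = sig$feature_id,
                              score = sig$log2FC),
                   all_measured = prot1$feature_id, pathways = pw,
                   n_boot = config$n_boot, seed = config$seed)
    .writeTsv(res, config$out_dir, "spia_results.tsv")
  })

  stage("survival", {
    pw <- PathwayGraph(
      pathwayId = "PLANTED",
      nodes = sprintf("NODE%02d", 1:8),
      edges = data.frame(source = sprintf("NODE%02d", 1:7),
                         target = sprintf("NODE%02d", 2:8), sign = 1,
                         relation = "activation",
                         stringsAsFactors = FALSE))
    sim <- simulateProtectiveCohort(pw, n_samples = 100,
                                    n_background = 100,
                                    seed = config$seed)
    cox <- coxFit(sim$survival)
    cut <- maxstatCutpoint(sim$survival, n_perm = config$n_perm,
                           seed = config$seed)
    high <- sim$survival$marker > cut$cutpoint
    km <- kmLogrank(sim$survival, high)
    gde <- groupDiffexp(sim$proteome, high)
    .writeTsv(cox, config$out_dir, "cox.tsv")
    .writeTsv(gde$table, config$out_dir, "group_de.tsv")
    jsonlite::write_json(list(cutpoint = cut$cutpoint, p = cut$p,
                              logrank_p = km$p),
                         file.path(config$out_dir, "cutpoint.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  manifest <- list(
    package = "ubiScreen",
    version = as.character(utils::packageVersion("ubiScreen")),
    seed = config$seed, n_cohorts = config$n_cohorts,
    thresholds = unclass(config$thresholds),
    stages = config$stages)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
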