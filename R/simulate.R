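## Synthetic multi-omics cohort generation. The generator plants known
## tumor/normal shifts, degradative E3-substrate couplings and prognostic
## markers so that every downstream stage can be validated against ground
## truth. Layers are conditionally independent given the plants.

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores the global RNG state so library code never perturbs the
#' caller's random stream.
#' @noRd
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Specification of a synthetic tumor/NAT multi-omics cohort
#'
#' Defaults describe the reference study conditions used throughout the test
#' suite: 80 tumor/NAT pairs, 800 proteins of which 60 are E3 ligases and 20
#' deubiquitinases, 5 substrates per E3 (300 interactions), a tenth of the
#' interactions degradative, planted shifts of 2 log2 units against residual
#' noise of 0.5, a shared subject effect of 0.3 giving paired designs their
#' power, and 10\% missingness.
#'
#' @param n_pairs number of tumor/NAT pairs (>= 3)
#' @param n_proteins total proteome features, including the enzymes
#' @param n_e3,n_dub number of E3 ligases / deubiquitinases
#' @param frac_e3_up fraction of E3s planted up-regulated in tumor
#' @param frac_dub_down fraction of DUBs planted down-regulated in tumor
#' @param esi_per_e3 substrates per E3 in the interaction network
#' @param frac_degradative fraction of all interactions planted as degradative
#'   (substrate sites up, protein down, mRNA flat; the E3 is drawn from the
#'   planted-up set so criterion (b) is attainable)
#' @param effect_log2fc planted tumor-normal shift, log2 units (> 0)
#' @param noise_sd residual abundance noise, log2 units
#' @param pair_sd SD of the shared subject random effect
#' @param missing_rate expected fraction of missing proteome/site cells
#' @param missing_mechanism \code{"MCAR"} or \code{"intensity"} (low-abundance
#'   cells more likely missing)
#' @param rna_dispersion negative-binomial dispersion of the RNA layer
#' @param seed integer RNG seed
#' @return a validated list of class \code{CohortSpec}
#' @export
cohortSpec <- function(n_pairs = 80, n_proteins = 800, n_e3 = 60, n_dub = 20,
                       frac_e3_up = 0.3, frac_dub_down = 0.3, esi_per_e3 = 5,
                       frac_degradative = 0.1, effect_log2fc = 2,
                       noise_sd = 0.5, pair_sd = 0.3, missing_rate = 0.1,
                       missing_mechanism = c("MCAR", "intensity"),
                       rna_dispersion = 0.1, seed = 1) {
  spec <- list(n_pairs = n_pairs, n_proteins = n_proteins, n_e3 = n_e3,
               n_dub = n_dub, frac_e3_up = frac_e3_up,
               frac_dub_down = frac_dub_down, esi_per_e3 = esi_per_e3,
               frac_degradative = frac_degradative,
               effect_log2fc = effect_log2fc, noise_sd = noise_sd,
               pair_sd = pair_sd, missing_rate = missing_rate,
               missing_mechanism = match.arg(missing_mechanism),
               rna_dispersion = rna_dispersion, seed = as.integer(seed))
  probs <- c(frac_e3_up, frac_dub_down, frac_degradative, missing_rate)
  if (any(probs < 0 | probs > 1)) stop("proportions must lie in [0, 1]")
  if (n_pairs < 3) stop("n_pairs must be >= 3")
  if (effect_log2fc <= 0) stop("effect_log2fc must be > 0")
  if (n_proteins < n_e3 + n_dub + n_e3 * esi_per_e3)
    stop("n_proteins too small for the requested enzymes and substrates")
  class(spec) <- "CohortSpec"
  spec
}

#' Simulate a paired tumor/NAT multi-omics cohort with planted ground truth
#'
#' Generates a log-scale proteome, an RNA count layer and a protein-corrected
#' ubiquitination-site layer over a shared paired design. Selected E3s are
#' shifted up and DUBs down in tumor; degradative substrates receive the
#' coupled pattern (sites up, protein down, mRNA flat) that the multi-omics
#' screen is designed to detect. Substrates are unique to their E3 so planted
#' calls are unambiguous.
#'
#' @param spec a [cohortSpec()]
#' @return list with elements \code{proteome}, \code{rna}, \code{sites}
#'   (\linkS4class{AbundanceExperiment}; RNA holds raw counts), \code{catalog}
#'   (\linkS4class{EnzymeCatalog}), \code{esi} (\linkS4class{ESINetwork}) and
#'   \code{truth} (plant record, test-only).
#' @export
simulateCohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  withSeed(spec$seed, {
    n <- spec$n_pairs
    e3 <- sprintf("E3_%03d", seq_len(spec$n_e3))
    dub <- sprintf("DUB_%03d", seq_len(spec$n_dub))
    n_sub <- spec$n_e3 * spec$esi_per_e3
    n_other <- spec$n_proteins - spec$n_e3 - spec$n_dub
    other <- sprintf("P%04d", seq_len(n_other))
    feats <- c(e3, dub, other)

    ## interaction network: substrates drawn without replacement so each
    ## belongs to exactly one E3
    subs <- sample(other, n_sub)
    esi_df <- data.frame(e3 = rep(e3, each = spec$esi_per_e3),
                         substrate = subs, source = "synthetic",
                         stringsAsFactors = FALSE)

    n_up <- round(spec$frac_e3_up * spec$n_e3)
    e3_up <- if (n_up) sample(e3, n_up) else character()
    n_dn <- round(spec$frac_dub_down * spec$n_dub)
    dub_down <- if (n_dn) sample(dub, n_dn) else character()

    n_deg <- round(spec$frac_degradative * nrow(esi_df))
    up_edges <- which(esi_df$e3 %in% e3_up)
    if (n_deg > length(up_edges))
      stop("frac_degradative requires more up-regulated E3 edges than exist; ",
           "raise frac_e3_up")
    deg_idx <- if (n_deg) sample(up_edges, n_deg) else integer()
    deg_pairs <- esi_df[deg_idx, c("e3", "substrate")]

    ## per-feature planted protein shift
    shift <- setNames(numeric(length(feats)), feats)
    shift[e3_up] <- spec$effect_log2fc
    shift[dub_down] <- -spec$effect_log2fc
    shift[deg_pairs$substrate] <- -spec$effect_log2fc

    samp_t <- sprintf("T%03d", seq_len(n))
    samp_n <- sprintf("N%03d", seq_len(n))
    design <- data.frame(
      sample_id = c(samp_t, samp_n), cohort = "SYN",
      condition = rep(c("tumor", "normal"), each = n),
      pair_id = rep(sprintf("pt%03d", seq_len(n)), 2),
      stringsAsFactors = FALSE)

    baseline <- rnorm(length(feats), 0, 1)
    subject <- matrix(rnorm(length(feats) * n, 0, spec$pair_sd),
                      length(feats), n)
    noise <- function() matrix(rnorm(length(feats) * n, 0, spec$noise_sd),
                               length(feats), n)
    prot <- cbind(baseline + subject + shift + noise(),
                  baseline + subject + noise())
    dimnames(prot) <- list(feats, c(samp_t, samp_n))

    ## RNA counts: NB means tied to protein baselines; degradative
    ## substrates keep a flat mRNA while their protein drops
    rna_shift <- shift
    rna_shift[deg_pairs$substrate] <- 0
    depth <- exp(rnorm(2 * n, 0, 0.2))
    mu_base <- 100 * 2^baseline
    mu <- cbind(matrix(mu_base * 2^rna_shift, length(feats), n),
                matrix(mu_base, length(feats), n))
    mu <- sweep(mu, 2, depth, `*`)
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / spec$rna_dispersion),
                     length(feats), 2 * n,
                     dimnames = list(feats, c(samp_t, samp_n)))

    ## ubiquitination sites: 1-3 per substrate, protein-corrected scale;
    ## degradative substrates get all their sites shifted up in tumor
    n_sites <- sample(1:3, length(subs), replace = TRUE)
    site_parent <- rep(subs, n_sites)
    site_ids <- paste0(site_parent, "_K",
                       unlist(lapply(n_sites, function(k)
                         sort(sample(1:999, k)))))
    site_shift <- ifelse(site_parent %in% deg_pairs$substrate,
                         spec$effect_log2fc, 0)
    sb <- rnorm(length(site_ids), 0, 1)
    ssub <- matrix(rnorm(length(site_ids) * n, 0, spec$pair_sd),
                   length(site_ids), n)
    snoise <- function() matrix(rnorm(length(site_ids) * n, 0, spec$noise_sd),
                                length(site_ids), n)
    sites <- cbind(sb + ssub + site_shift + snoise(), sb + ssub + snoise())
    dimnames(sites) <- list(site_ids, c(samp_t, samp_n))

    proteome <- AbundanceExperiment(prot, design)
    site_ae <- AbundanceExperiment(sites, design)
    if (spec$missing_rate > 0) {
      proteome <- maskMissing(proteome, spec$missing_rate,
                              spec$missing_mechanism,
                              seed = sample.int(.Machine$integer.max, 1))
      site_ae <- maskMissing(site_ae, spec$missing_rate,
                             spec$missing_mechanism,
                             seed = sample.int(.Machine$integer.max, 1))
    }

    direction <- function(s) ifelse(s > 0, "up", ifelse(s < 0, "down", "null"))
    truth <- list(
      protein_direction = direction(shift),
      rna_direction = direction(rna_shift),
      site_direction = setNames(direction(site_shift), site_ids),
      e3_up = e3_up, dub_down = dub_down,
      degradative = deg_pairs,
      marker = NA_character_, marker_loghr = NA_real_)

    list(proteome = proteome,
         rna = AbundanceExperiment(counts, design),
         sites = site_ae,
         catalog = EnzymeCatalog(e3 = e3, dub = dub),
         esi = ESINetwork(edges = esi_df),
         truth = truth)
  })
}

#' Mask abundance cells as missing
#'
#' @param matrix an \linkS4class{AbundanceExperiment}
#' @param rate expected fraction of masked cells, in \[0, 1)
#' @param mechanism \code{"MCAR"} masks uniformly at random;
#'   \code{"intensity"} masks with probability logistic-decreasing in
#'   abundance, calibrated so the expected overall rate matches \code{rate}.
#' @param seed integer RNG seed
#' @return the matrix with additional \code{NA} cells
#' @export
maskMissing <- function(matrix, rate, mechanism = c("MCAR", "intensity"),
                        seed = 1) {
  mechanism <- match.arg(mechanism)
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)")
  if (rate == 0) return(matrix)
  m <- abundance(matrix)
  withSeed(seed, {
    obs <- which(!is.na(m))
    if (mechanism == "MCAR") {
      p <- rep(rate, length(obs))
    } else {
      z <- scale(as.vector(m[obs]))[, 1]
      slope <- 1.5   # logistic steepness on z-scaled abundance
      f <- function(a) mean(stats::plogis(a - slope * z)) - rate
      a <- stats::uniroot(f, c(-30, 30))$root
      p <- stats::plogis(a - slope * z)
    }
    mask <- obs[runif(length(obs)) < p]
    m[mask] <- NA_real_
  })
  AbundanceExperiment(m, sampleDesign(matrix))
}

#' Simulate survival with an exponential proportional-hazards marker effect
#'
#' Marker values are standard normal; event times are exponential with hazard
#' proportional to \code{exp(beta * marker)}; a fraction \code{censor_rate}
#' of records is independently right-censored at a uniform time before the
#' event.
#'
#' @param n number of subjects (>= 10)
#' @param beta true log-hazard per marker unit
#' @param censor_rate fraction censored, in \[0, 1)
#' @param seed integer RNG seed
#' @return a data.frame passing [survivalTable()]
#' @export
simulateSurvival <- function(n, beta, censor_rate = 0.2, seed = 1) {
  if (n < 10) stop("n must be >= 10")
  if (censor_rate >= 1 || censor_rate < 0) stop("censor_rate must lie in [0, 1)")
  withSeed(seed, {
    marker <- rnorm(n)
    t_event <- rexp(n, rate = 0.1 * exp(beta * marker))
    cens <- runif(n) < censor_rate
    time <- ifelse(cens, runif(n) * t_event, t_event)
    survivalTable(data.frame(
      sample_id = sprintf("S%04d", seq_len(n)),
      time = time, event = as.integer(!cens), marker = marker,
      stringsAsFactors = FALSE))
  })
}

#' Simulate multi-cohort proteomes with tumor convergence
#'
#' Emulates reduced tissue specificity of tumor expression: every feature has
#' a cohort-specific baseline offset that applies fully to normal samples but
#' is attenuated by \code{convergence} in tumor samples, plus a tumor shift
#' shared across cohorts. With strong convergence, normal samples separate by
#' cohort while tumor samples collapse toward a shared profile, so sample
#' clustering finds fewer tumor clusters than normal clusters.
#'
#' @param n_cohorts number of cohorts
#' @param n_features number of proteins
#' @param n_tumor,n_normal samples per cohort and condition
#' @param cohort_sd SD of the cohort-specific baseline offsets
#' @param convergence in \[0, 1\]; 1 removes cohort offsets from tumor
#'   samples entirely
#' @param noise_sd residual noise SD
#' @param seed integer RNG seed
#' @return an \linkS4class{AbundanceExperiment} pooling all cohorts
#' @export
simulateTissueCohorts <- function(n_cohorts = 6, n_features = 150,
                                  n_tumor = 20, n_normal = 20,
                                  cohort_sd = 2, convergence = 0.9,
                                  noise_sd = 0.5, seed = 1) {
  withSeed(seed, {
    feats <- sprintf("P%04d", seq_len(n_features))
    base <- rnorm(n_features)
    tumor_shift <- rnorm(n_features, 0, 1)
    mats <- list(); designs <- list()
    for (k in seq_len(n_cohorts)) {
      off <- rnorm(n_features, 0, cohort_sd)
      co <- sprintf("C%02d", k)
      ids_t <- sprintf("%s_T%02d", co, seq_len(n_tumor))
      ids_n <- sprintf("%s_N%02d", co, seq_len(n_normal))
      mt <- base + (1 - convergence) * off + tumor_shift +
        matrix(rnorm(n_features * n_tumor, 0, noise_sd), n_features)
      mn <- base + off +
        matrix(rnorm(n_features * n_normal, 0, noise_sd), n_features)
      m <- cbind(mt, mn)
      dimnames(m) <- list(feats, c(ids_t, ids_n))
      mats[[k]] <- m
      designs[[k]] <- data.frame(
        sample_id = c(ids_t, ids_n), cohort = co,
        condition = rep(c("tumor", "normal"), c(n_tumor, n_normal)),
        pair_id = NA_character_, stringsAsFactors = FALSE)
    }
    AbundanceExperiment(do.call(cbind, mats), do.call(rbind, designs))
  })
}

#' Simulate an ESI-coupled proteome with tumor rewiring
#'
#' In normal samples each substrate tracks its E3 through a shared latent
#' component (Spearman correlation well away from zero); in tumor samples the
#' coupling is rewired (substrates independent of their E3), so the tumor
#' distribution of E3-substrate correlations concentrates near zero.
#'
#' @param n_e3 number of E3s
#' @param subs_per_e3 substrates per E3
#' @param n_samples samples per condition
#' @param coupling coupling weight of substrate on E3 in normal samples
#' @param noise_sd residual noise SD
#' @param seed integer RNG seed
#' @return list with \code{proteome} (\linkS4class{AbundanceExperiment},
#'   tumor + normal samples) and \code{esi} (\linkS4class{ESINetwork})
#' @export
simulateRewiredESI <- function(n_e3 = 30, subs_per_e3 = 5, n_samples = 60,
                               coupling = 0.8, noise_sd = 0.5, seed = 1) {
  withSeed(seed, {
    e3 <- sprintf("E3_%03d", seq_len(n_e3))
    subs <- sprintf("SUB_%04d", seq_len(n_e3 * subs_per_e3))
    esi_df <- data.frame(e3 = rep(e3, each = subs_per_e3), substrate = subs,
                         source = "synthetic", stringsAsFactors = FALSE)
    ids_t <- sprintf("T%03d", seq_len(n_samples))
    ids_n <- sprintf("N%03d", seq_len(n_samples))
    e3_t <- matrix(rnorm(n_e3 * n_samples), n_e3)
    e3_n <- matrix(rnorm(n_e3 * n_samples), n_e3)
    sub_t <- matrix(rnorm(length(subs) * n_samples, 0, 1), length(subs))
    sub_n <- coupling * e3_n[rep(seq_len(n_e3), each = subs_per_e3), ] +
      matrix(rnorm(length(subs) * n_samples, 0, noise_sd), length(subs))
    m <- rbind(cbind(e3_t, e3_n), cbind(sub_t, sub_n))
    dimnames(m) <- list(c(e3, subs), c(ids_t, ids_n))
    design <- data.frame(
      sample_id = c(ids_t, ids_n), cohort = "SYN",
      condition = rep(c("tumor", "normal"), each = n_samples),
      pair_id = NA_character_, stringsAsFactors = FALSE)
    list(proteome = AbundanceExperiment(m, design),
         esi = ESINetwork(edges = esi_df))
  })
}

#' Simulate a cohort with a protective marker suppressing a pathway
#'
#' Generates tumor-sample proteomes in which a planted marker protein (a
#' protective E3) suppresses the nodes of one pathway: high-marker samples
#' have the pathway's proteins shifted down by \code{effect}, and survival
#' improves with the marker (negative log-hazard). The full prognosis
#' workflow (Cox fit, maximally selected cutpoint, between-group differential
#' expression, pathway impact analysis) should rediscover the pathway as
#' Inhibited.
#'
#' @param pathway a \linkS4class{PathwayGraph} whose nodes are planted
#' @param n_samples number of tumor samples
#' @param n_background additional unaffected proteins
#' @param effect downward shift of pathway nodes per marker SD above the
#'   median, log2 units
#' @param beta true log-hazard per marker unit (negative = protective)
#' @param noise_sd residual noise SD
#' @param censor_rate censoring fraction
#' @param seed integer RNG seed
#' @return list with \code{proteome} (tumor samples only), \code{survival}
#'   (marker column = planted marker abundance) and \code{marker} (symbol)
#' @export
simulateProtectiveCohort <- function(pathway, n_samples = 120,
                                     n_background = 300, effect = 1.5,
                                     beta = -0.8, noise_sd = 0.5,
                                     censor_rate = 0.2, seed = 1) {
  withSeed(seed, {
    marker <- "TRIM_MARKER"
    nodes <- setdiff(pathwayNodes(pathway), marker)
    bg <- sprintf("BG%04d", seq_len(n_background))
    feats <- c(marker, nodes, bg)
    mval <- rnorm(n_samples)
    high <- as.numeric(mval > median(mval))
    m <- matrix(rnorm(length(feats) * n_samples, 0, noise_sd),
                length(feats), n_samples,
                dimnames = list(feats, sprintf("T%03d", seq_len(n_samples))))
    m[marker, ] <- mval
    m[nodes, ] <- sweep(m[nodes, , drop = FALSE], 2, effect * high, `-`)
    t_event <- rexp(n_samples, rate = 0.1 * exp(beta * mval))
    cens <- runif(n_samples) < censor_rate
    design <- data.frame(sample_id = colnames(m), cohort = "SYN",
                         condition = "tumor", pair_id = NA_character_,
                         stringsAsFactors = FALSE)
    surv <- survivalTable(data.frame(
      sample_id = colnames(m),
      time = ifelse(cens, runif(n_samples) * t_event, t_event),
      event = as.integer(!cens), marker = mval, stringsAsFactors = FALSE))
    list(proteome = AbundanceExperiment(m, design), survival = surv,
         marker = marker)
  })
}
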