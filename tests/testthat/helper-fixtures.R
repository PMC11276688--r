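# Shared fixture builders. All data are generated in code; nothing binary.

tinyDesign <- function(n_pairs, cohort = "SYN") {
  data.frame(
    sample_id = c(sprintf("T%02d", seq_len(n_pairs)),
                  sprintf("N%02d", seq_len(n_pairs))),
    cohort = cohort,
    condition = rep(c("tumor", "normal"), each = n_pairs),
    pair_id = rep(sprintf("p%02d", seq_len(n_pairs)), 2),
    stringsAsFactors = FALSE)
}

tinyAE <- function(values, n_pairs = ncol(values) / 2, cohort = "SYN") {
  d <- tinyDesign(n_pairs, cohort)
  colnames(values) <- d$sample_id
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("F%03d", seq_len(nrow(values)))
  AbundanceExperiment(values, d)
}

chainPathway <- function(n = 3, signs = rep(1, n - 1), id = "CHAIN") {
  nodes <- LETTERS[seq_len(n)]
  PathwayGraph(pathwayId = id, nodes = nodes,
               edges = data.frame(source = nodes[-n], target = nodes[-1],
                                  sign = signs,
                                  relation = ifelse(signs > 0, "activation",
                                                    "inhibition"),
                                  stringsAsFactors = FALSE))
}

# independent brute-force two-sided exact signed-rank p over all sign patterns
bruteSignedRankP <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  grid <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(grid) %*% r
  mean_w <- n * (n + 1) / 4
  min(1, mean(abs(w_all - mean_w) >= abs(w_obs - mean_w) - 1e-9))
}

# independent step-up BH
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  cummin_rev <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q[o] <- pmin(1, cummin_rev)
  q
}
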