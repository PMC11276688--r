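mkRow <- function(fc, q) data.frame(feature_id = "X", log2FC = fc, q = q)
mkSites <- function(fc, q, ids = sprintf("X_K%d", seq_along(fc)))
  data.frame(feature_id = ids, log2FC = fc, q = q)

test_that("the strict/non-strict 0.5 fold-change boundary is honored per step", {
  cat_ <- EnzymeCatalog(e3 = c("EDGE", "IN"), dub = "D1")
  de <- data.frame(feature_id = c("EDGE", "IN"),
                   log2FC = c(0.5, 0.8), p = c(0.001, 0.001),
                   q = c(0.005, 0.005))
  sel <- selectSignificantE3(de, cat_)
  expect_false("EDGE" %in% sel$up)    # significance uses strict > 0.5
  expect_true("IN" %in% sel$up)

  # criterion (b) is non-strict >= 0.5: the same E3 stats qualify there
  cl <- classifyESI(site_rows = mkSites(0.3, 0.01),
                    e3_row = mkRow(0.5, 0.005),
                    prot_row = mkRow(-0.8, 0.005),
                    rna_row = mkRow(0.1, 0.4))
  expect_equal(cl$call, "degradative")
})

test_that("classification reproduces the canonical degradative patterns", {
  # branch 1: protein down, mRNA not significantly down
  cl1 <- classifyESI(mkSites(0.3, 0.01), mkRow(0.6, 0.001),
                     mkRow(-0.8, 0.005), mkRow(0.1, 0.4))
  expect_equal(cl1$call, "degradative")
  expect_equal(cl1$branch, "protein_down_mrna_not_down")

  # failing criterion (a): site not significant
  cl2 <- classifyESI(mkSites(0.3, 0.2), mkRow(0.6, 0.001),
                     mkRow(-0.8, 0.005), mkRow(0.1, 0.4))
  expect_equal(cl2$call, "none")

  # branch 2: protein flat, mRNA significantly up
  cl3 <- classifyESI(mkSites(0.3, 0.01), mkRow(0.6, 0.001),
                     mkRow(-0.1, 0.5), mkRow(1.2, 0.001))
  expect_equal(cl3$call, "degradative")
  expect_equal(cl3$branch, "protein_flat_mrna_up")

  # over-ubiquitinated but protein down AND mRNA significantly down: not
  # degradative via branch 1; branch 2 needs flat protein
  cl4 <- classifyESI(mkSites(0.3, 0.01), mkRow(0.6, 0.001),
                     mkRow(-0.8, 0.005), mkRow(-1.2, 0.001))
  expect_equal(cl4$call, "over_ubiquitinated")

  # missing layers produce distinct reason codes
  expect_equal(classifyESI(NULL, mkRow(1, 0.001), mkRow(-1, 0.001),
                           mkRow(0, 0.5))$reason, "no_sites")
  expect_equal(classifyESI(mkSites(1, 0.01), NULL, mkRow(-1, 0.001),
                           mkRow(0, 0.5))$reason, "no_e3_protein")
  expect_equal(classifyESI(mkSites(1, 0.01), mkRow(1, 0.001), NULL,
                           mkRow(0, 0.5))$reason, "no_substrate_protein")
  expect_equal(classifyESI(mkSites(1, 0.01), mkRow(1, 0.001),
                           mkRow(-1, 0.001), NULL)$reason,
               "no_substrate_rna")
})

test_that("any single qualifying site satisfies criterion (a)", {
  cl <- classifyESI(mkSites(c(-1, 0.4, 0.2), c(0.001, 0.02, 0.8)),
                    mkRow(0.9, 0.001), mkRow(-0.5, 0.001), mkRow(0, 0.9))
  expect_equal(cl$call, "degradative")
  expect_equal(cl$sites_passing, "X_K2")
})

test_that("screen calls nest and tighten monotonically with thresholds", {
  sp <- cohortSpec(n_pairs = 30, n_proteins = 400, missing_rate = 0,
                   seed = 41)
  sim <- simulateCohort(sp)
  pd <- testDifferential(sim$proteome, paired = TRUE)
  sd_ <- testSites(sim$sites)
  rd <- testRNA(sim$rna)
  res <- runScreen(sim$esi, sd_, pd, rd)
  calls <- res$calls
  deg <- calls$call == "degradative"
  over <- calls$call %in% c("degradative", "over_ubiquitinated")
  expect_true(all(which(deg) %in% which(over)))
  expect_true(all(nzchar(calls$sites_passing[deg])))

  tighter <- runScreen(sim$esi, sd_, pd, rd,
                       thresholds = screenThresholds(site_q_max = 0.01,
                                                     e3_q_max = 0.001,
                                                     prot_q_max = 0.001,
                                                     rna_q_max = 0.001))
  expect_lte(sum(tighter$calls$call == "degradative"), sum(deg))
  expect_lte(sum(tighter$calls$call != "none" &
                   tighter$calls$call != "skipped"), sum(over))

  # summary counts distinct enzymes and substrates
  expect_equal(res$summary$n_pairs[res$summary$call == "degradative"],
               sum(deg))
  expect_error(runScreen(ESINetwork(edges = data.frame(
    e3 = character(), substrate = character(), source = character())),
    sd_, pd, rd), "empty ESI")
  expect_error(runScreen(sim$esi, sd_, pd, NULL), "rna_de")
})

test_that("threshold constructor rejects out-of-range q bounds", {
  expect_error(screenThresholds(site_q_max = 0), "q thresholds")
  expect_error(screenThresholds(e3_q_max = 1.5), "q thresholds")
})
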