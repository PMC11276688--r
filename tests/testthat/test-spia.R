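test_that("influence matrices encode signed edges and out-degrees", {
  g <- chainPathway(3)          # A -> B -> C, both activation
  inf <- buildInfluence(g)
  expect_equal(unname(inf$n_ds), c(1, 1, 0))
  expect_equal(inf$beta["B", "A"], 1)
  expect_equal(inf$beta["C", "B"], 1)

  gi <- chainPathway(2, signs = -1)
  expect_equal(buildInfluence(gi)$beta["B", "A"], -1)

  # brute-force edge replay on random graphs
  set.seed(55)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    nodes <- sprintf("N%02d", seq_len(n))
    ne <- sample(3:10, 1)
    e <- unique(data.frame(source = sample(nodes, ne, TRUE),
                           target = sample(nodes, ne, TRUE),
                           stringsAsFactors = FALSE))
    e <- e[e$source != e$target, , drop = FALSE]
    if (!nrow(e)) next
    e$sign <- sample(c(-1, 1), nrow(e), TRUE)
    e$relation <- "x"
    g <- PathwayGraph(pathwayId = "R", nodes = nodes, edges = e)
    inf <- buildInfluence(g)
    beta_brute <- matrix(0, n, n, dimnames = list(nodes, nodes))
    for (i in seq_len(nrow(e)))
      beta_brute[e$target[i], e$source[i]] <- e$sign[i]
    expect_identical(inf$beta, beta_brute)
    expect_equal(unname(inf$n_ds),
                 unname(colSums(beta_brute != 0)))
  }
})

test_that("perturbation propagation matches hand-solved linear systems", {
  g <- chainPathway(3)
  np <- netPerturbation(c(A = 1, B = 0, C = 0), buildInfluence(g)$B)
  expect_equal(unname(np$pf), c(1, 1, 1))
  expect_equal(unname(np$acc), c(0, 1, 1))
  expect_equal(np$t_a, 2)

  gi <- chainPathway(2, signs = -1)
  npi <- netPerturbation(c(A = 1, B = 0), buildInfluence(gi)$B)
  expect_equal(unname(npi$acc["B"]), -1)
  expect_equal(npi$t_a, -1)

  expect_equal(netPerturbation(c(A = 0, B = 0, C = 0),
                               buildInfluence(g)$B)$t_a, 0)
})

test_that("the solver agrees with fixed-point iteration on acyclic graphs", {
  set.seed(61)
  for (rep in 1:20) {
    n <- sample(4:9, 1)
    nodes <- sprintf("N%02d", seq_len(n))
    # random DAG: edges only forward in index order
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    take <- pairs[sample(nrow(pairs), min(nrow(pairs), sample(3:8, 1))), ,
                  drop = FALSE]
    e <- data.frame(source = nodes[take[, 1]], target = nodes[take[, 2]],
                    sign = sample(c(-1, 1), nrow(take), TRUE),
                    relation = "x", stringsAsFactors = FALSE)
    g <- PathwayGraph(pathwayId = "DAG", nodes = nodes, edges = e)
    B <- buildInfluence(g)$B
    de <- setNames(rnorm(n) * rbinom(n, 1, 0.5), nodes)
    np <- netPerturbation(de, B)
    pf <- de
    for (it in 1:200) pf <- de + as.vector(B %*% pf)
    expect_equal(np$pf, pf, tolerance = 1e-10)
    # sign symmetry: negating all inputs negates tA exactly
    expect_equal(netPerturbation(-de, B)$t_a, -np$t_a)
  }
})

test_that("over-representation tail is exact and shared with the ORA kernel", {
  expect_equal(pNDE(0, 5, 5, 20), 1)
  expect_equal(pNDE(5, 5, 5, 20), 1 / choose(20, 5), tolerance = 1e-12)
  uni <- sprintf("G%02d", 1:20)
  gs <- GeneSetCollection(sets = list(S = uni[1:5]),
                          descriptions = c(S = ""))
  expect_equal(pNDE(3, 5, 8, 20),
               oraEnrich(c(uni[1:3], uni[10:14]), uni, gs)$p)
  expect_error(pNDE(6, 5, 8, 20), "inconsistent")
})

test_that("bootstrap pPERT matches exhaustive enumeration on the 3-node chain", {
  g <- chainPathway(3)
  # single DE value on the source: tA_obs = 2v; the 3 possible assignments
  # give tA in {2v, v, 0}
  v <- 1.7
  pp <- pPert(g, c(A = v), n_boot = 2000, seed = 9)
  expect_equal(pp$t_a_obs, 2 * v)
  enum_ta <- c(2 * v, v, 0)
  med <- median(enum_ta)
  p_enum <- mean(abs(enum_ta - med) >= abs(2 * v - med))
  mc_se <- sqrt(p_enum * (1 - p_enum) / 2000)
  expect_lt(abs(pp$p_pert - p_enum), 2 * mc_se + 1 / 2001)

  pp2 <- pPert(g, c(A = v), n_boot = 2000, seed = 9)
  expect_identical(pp$p_pert, pp2$p_pert)
  expect_error(pPert(g, c(A = 1, B = 1, C = 1, D = 1)), "exceeds|unused")
})

test_that("Fisher combination matches the chi-square tail", {
  expect_equal(combineFisher(1, 1), 1)
  expect_equal(combineFisher(0.1, 0.1), 0.01 - 0.01 * log(0.01))
  set.seed(3)
  for (rep in 1:100) {
    p1 <- runif(1); p2 <- runif(1)
    cc <- p1 * p2
    expect_equal(combineFisher(p1, p2),
                 pchisq(-2 * log(cc), df = 4, lower.tail = FALSE),
                 tolerance = 1e-9)
  }
  # monotone in the product
  cs <- sort(runif(50))
  pg <- cs - cs * log(cs)
  expect_true(all(diff(pg) > 0))
})

test_that("planted activation cascades rank first and null lists calibrate", {
  set.seed(71)
  target <- chainPathway(8, id = "TARGET")
  bg <- makeDemoPathways(4, 8, seed = 5)
  measured <- c(pathwayNodes(target),
                unlist(lapply(bg, pathwayNodes)),
                sprintf("BGX%03d", 1:150))
  de <- data.frame(symbol = pathwayNodes(target)[1:5],
                   score = rep(2, 5))
  res <- runSPIA(de, measured, c(list(target), bg), n_boot = 500, seed = 2)
  expect_equal(res$pathway_id[1], "TARGET")
  expect_equal(res$status[res$pathway_id == "TARGET"], "Activated")
  expect_true(all(res[res$NDE == 0, c("pNDE", "pPERT")] == 1))
  expect_true(all(res$tA[res$NDE == 0] == 0))

  res2 <- runSPIA(de, measured, c(list(target), bg), n_boot = 500, seed = 2)
  expect_identical(res, res2)
  expect_error(runSPIA(de, measured, list()), "empty pathway")
  expect_error(runSPIA(data.frame(symbol = "NOPE", score = 1),
                       measured, bg), "subset")
})
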