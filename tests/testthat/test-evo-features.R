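test_that("Sankoff costs match hand traces and basic invariants", {
  t4 <- datedTree("((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(unname(sankoffCost(c(A = 1, B = 1, C = 1, D = 1), t4, 1, 3)), 0)
  expect_equal(unname(sankoffCost(c(A = 1, B = 1, C = 0, D = 0), t4, 1, 3)), 1)
  # missing tips are free
  expect_equal(unname(sankoffCost(c(A = 1, B = 2, C = 2, D = 2), t4, 1, 3)), 0)
  expect_error(sankoffCost(c(A = 1, E = 0), t4), "unknown species")
})

test_that("Sankoff equals exhaustive enumeration on random small trees", {
  set.seed(21)
  for (case in 1:120) {
    nt <- sample(4:6, 1)
    tr <- randomDatedTree(nt)
    pat <- stats::setNames(sample(0:2, nt, replace = TRUE, prob = c(.4, .4, .2)),
                           leafNames(tr))
    gl <- sample(list(c(1, 3), c(3, 1), c(2, 5)), 1)[[1]]
    expect_equal(unname(sankoffCost(pat, tr, gl[1], gl[2])),
                 bruteSankoff(pat, tr, gl[1], gl[2]))
  }
})

test_that("cost with (g,l) equals cost with (l,g) on the complemented pattern", {
  set.seed(4)
  for (case in 1:40) {
    tr <- randomDatedTree(5)
    pat <- stats::setNames(sample(0:2, 5, replace = TRUE), leafNames(tr))
    comp <- pat
    comp[pat == 0L] <- 1L; comp[pat == 1L] <- 0L
    expect_equal(unname(sankoffCost(pat, tr, 1, 3)),
                 unname(sankoffCost(comp, tr, 3, 1)))
  }
})

test_that("Dollo LCA age is the MRCA age of intron-bearing species", {
  tr <- datedTree("((A:1,B:1):1,C:2);")
  expect_equal(unname(dolloLcaAge(c(A = 1, B = 0, C = 0), tr)), 0)
  expect_equal(unname(dolloLcaAge(c(A = 1, B = 0, C = 1), tr)), 2)
  expect_equal(unname(dolloLcaAge(c(A = 1, B = 1, C = 1), tr)), 2)
  expect_error(dolloLcaAge(c(A = 0, B = 0, C = 0), tr), "no species")
  # adding 1s weakly increases the age
  set.seed(14)
  tr8 <- randomDatedTree(8)
  for (i in 1:20) {
    pat <- stats::setNames(rep(0L, 8), leafNames(tr8))
    pat[sample(8, sample(1:7, 1))] <- 1L
    pat2 <- pat
    pat2[sample(which(pat == 0L), 1)] <- 1L
    expect_lte(unname(dolloLcaAge(pat, tr8)), unname(dolloLcaAge(pat2, tr8)))
  }
})

test_that("presence-ratio and clade features follow their definitions", {
  v <- rbind(c(a = 1, b = 1, c = 0, d = 2))
  cf <- cladeFeatures(v, list(g1 = c("c", "d"), g2 = c("a")))
  expect_equal(cf$ONES_KNOWN, 2 / 3)
  expect_equal(cf$IN_G1, 0L)       # members are 0 or 2
  expect_equal(cf$IN_G2, 1L)
  expect_equal(cladeFeatures(rbind(c(a = 1, b = 1, c = 2)),
                             list())$ONES_KNOWN, 1)
  expect_error(cladeFeatures(rbind(c(a = 2, b = 2)), list()), "undefined")
  expect_error(cladeFeatures(v, list(g = "zz")), "zz")
})

test_that("pruning log-likelihood matches brute force and normalises", {
  # one leaf, zero-length branch: log pi1
  t1 <- datedTree("(A:0);")
  m <- gainLossModel(0.4, 0.6, pi1 = 0.3)
  expect_equal(unname(patternLogLik(c(A = 1), t1, m)), log(0.3))
  expect_equal(unname(patternLogLik(c(A = 0), t1, m)), log(0.7))

  set.seed(77)
  for (case in 1:40) {
    nt <- sample(3:5, 1)
    tr <- randomDatedTree(nt)
    g <- stats::runif(1, 0.05, 1); l <- stats::runif(1, 0.05, 1)
    pi1 <- stats::runif(1, 0.1, 0.9)
    mm <- gainLossModel(g, l, pi1)
    pat <- stats::setNames(sample(0:2, nt, replace = TRUE), leafNames(tr))
    expect_equal(unname(patternLogLik(pat, tr, mm)),
                 bruteLogLik(pat, tr, g, l, pi1), tolerance = 1e-10)
  }
  # exponentials over all observable tip patterns sum to 1
  tr <- randomDatedTree(4, seed = 3)
  mm <- gainLossModel(0.3, 0.8, 0.4)
  pats <- as.matrix(expand.grid(rep(list(0:1), 4)))
  colnames(pats) <- leafNames(tr)
  ll <- patternLogLik(pats, tr, mm)
  expect_true(all(ll <= 0))
  expect_equal(sum(exp(ll)), 1, tolerance = 1e-12)
})

test_that("gain/loss rates are recovered from simulated patterns", {
  tr <- exampleTree()
  v <- simulateGainLoss(tr, 2000, gain = 3e-4, loss = 6e-4, seed = 55)
  fit <- fitGainLoss(v, tr)
  expect_lt(abs(fit@gain - 3e-4) / 3e-4, 0.25)
  expect_lt(abs(fit@loss - 6e-4) / 6e-4, 0.25)
  # optimality: fitted likelihood at least that of the true parameters
  true_ll <- sum(patternLogLik(v, tr, gainLossModel(3e-4, 6e-4)))
  expect_gte(fit@logLik, true_ll - 1e-6)
  # loss-free simulation (stationary root, as the model assumes) drives the
  # loss estimate to (nearly) zero
  v0 <- simulateGainLoss(tr, 1500, gain = 4e-4, loss = 0, seed = 9)
  fit0 <- fitGainLoss(v0, tr)
  expect_lte(fit0@loss, fit0@gain / 10)
})

test_that("position medians follow the stated conventions", {
  v <- rbind(c(Homo_sapiens = 1, b = 0))
  one <- collapsePatterns(makeCols(v, position = 265L, cds_length = 1000L))
  pf <- positionFeatures(one)
  expect_equal(pf$MED_POSITION, 265)
  expect_equal(pf$MED_REL_POSITION, 0.265)

  v3 <- v[rep(1, 3), , drop = FALSE]
  odd <- collapsePatterns(makeCols(v3, position = c(100L, 200L, 400L),
                                   cds_length = 1000L))
  expect_equal(positionFeatures(odd)$MED_POSITION, 200)
  v2 <- v[rep(1, 2), , drop = FALSE]
  even <- collapsePatterns(makeCols(v2, position = c(100L, 300L),
                                    cds_length = 1000L))
  expect_equal(positionFeatures(even)$MED_POSITION, 200)  # mean of middle two
})

test_that("the feature table has 13 deterministic columns", {
  sim <- simulatePatterns(simConfig(nSets = 25, seed = 6))
  tr <- exampleTree()
  model <- fitGainLoss(sim$patterns, tr)
  ft <- buildFeatureTable(sim$patterns, tr, exampleClades(), model)
  expect_equal(ncol(ft), 13L)
  expect_equal(colnames(ft),
               c("LOG_LIKE", "ONES_KNOWN", "SANKOFF_G1L3", "SANKOFF_G3L1",
                 "IN_AMPHIBIAN", "IN_FISH", "IN_BIRD", "IN_FUNGI", "IN_PLANT",
                 "IN_PROTIST", "LCA_AGE", "MED_POSITION", "MED_REL_POSITION"))
  expect_equal(nrow(ft), nPatterns(sim$patterns))
  expect_true(all(ft$LOG_LIKE <= 0))
  expect_true(all(ft$ONES_KNOWN >= 0 & ft$ONES_KNOWN <= 1))
  expect_identical(ft, buildFeatureTable(sim$patterns, tr, exampleClades(), model))
})

test_that("standardization freezes and re-applies its parameters", {
  set.seed(2)
  x <- cbind(cont = rnorm(50, 5, 2), bin = rbinom(50, 1, 0.4))
  std <- standardizeFeatures(x)
  expect_equal(unname(std$center["bin"]), 0)
  expect_equal(unname(std$scale["bin"]), 1)
  expect_equal(mean(std$x[, "cont"]), 0, tolerance = 1e-12)
  again <- standardizeFeatures(x, std$center, std$scale)
  expect_equal(again$x, std$x)
})
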