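test_that("the logistic response follows the printed sign convention", {
  expect_equal(probFunctional(0, omega = 0, omega0 = 0), 0.5)
  expect_equal(probFunctional(2, omega = 1, omega0 = 0), 1 / (1 + exp(-2)),
               tolerance = 1e-9)
  # omega0 enters the exponent with a plus sign: it lowers the probability
  expect_equal(probFunctional(0, omega = 1, omega0 = 2), stats::plogis(-2))
  # strictly increasing in omega' x
  xs <- seq(-5, 5, by = 0.5)
  ps <- probFunctional(matrix(xs), omega = 1.3, omega0 = 0.4)
  expect_true(all(diff(ps) > 0))
  expect_error(probFunctional(c(1, 2), omega = 1, omega0 = 0), "mismatch")
  # numerically stable at extreme arguments
  expect_equal(probFunctional(1000, omega = 1, omega0 = 0), 1)
  expect_equal(probFunctional(-1000, omega = 1, omega0 = 0), 0)
})

test_that("the observed log-likelihood matches a hand computation", {
  x <- matrix(c(0.5, -1, 2), ncol = 1)
  z <- c(1L, 0L, 0L)
  om <- 1.2; om0 <- -0.3; th <- 0.4
  p <- 1 / (1 + exp(-(om * x[, 1]) + om0))
  hand <- log(th * p[1]) + log(1 - th * p[2]) + log(1 - th * p[3])
  expect_equal(observedLogLik(x, z, om, om0, th), hand, tolerance = 1e-12)
  expect_lte(observedLogLik(x, z, om, om0, th), 0)
  # noiseless limit: the standard logistic log-likelihood
  std <- sum(log(ifelse(z == 1, p, 1 - p)))
  expect_equal(observedLogLik(x, z, om, om0, 1), std, tolerance = 1e-12)
  # theta11 = 0 with an observed 1 is a defined -Inf, not a crash
  expect_equal(observedLogLik(x, z, om, om0, 0), -Inf)
})

test_that("E-step responsibilities follow the one-sided noise structure", {
  x <- matrix(c(1, 1), ncol = 1)
  expect_equal(eStep(x, c(1L, 1L), 0.5, 0, 0.3), c(1, 1))
  # theta11 = 0 and z = 0: the label carries no information
  p <- probFunctional(x, 0.8, 0.1)
  expect_equal(eStep(x, c(0L, 0L), 0.8, 0.1, 0), p)
  # numeric case: p1 = 0.8, theta11 = 0.25, z = 0 -> 0.75
  x1 <- matrix(log(4), 1, 1)  # plogis(log 4) = 0.8
  expect_equal(eStep(x1, 0L, 1, 0, 0.25), 0.75, tolerance = 1e-12)
  expect_error(eStep(x, c(1L, 0L), 0.5, 0, 0), "degenerate")
})

test_that("the theta11 update is the responsibility-weighted label rate", {
  expect_equal(mStepTheta(c(1, 0, 1), c(1L, 0L, 1L)), 1)
  expect_equal(mStepTheta(c(1, 1, 0.5), c(1L, 0L, 0L)), 1 / 2.5)
})

test_that("EM trajectories are monotone and reach the direct optimum", {
  for (seed in c(2, 5, 9)) {
    sim <- simulateFeatures(150, c(1.2, -0.8), omega0 = 0.2, theta11 = 0.4,
                            seed = seed)
    fit <- fitNoisyLogistic(sim$x, sim$z, restarts = 3, seed = seed)
    expect_true(all(diff(fit@trajectory) >= -1e-8))
    direct <- directNoisyOpt(sim$x, sim$z)
    expect_equal(fit@logLik, direct, tolerance = 1e-3)
  }
})

test_that("with theta11 fixed at 1 the fit is exactly a plain logistic fit", {
  sim <- simulateFeatures(400, c(1.5, -1), omega0 = 0.3, theta11 = 1, seed = 12)
  fit <- fitNoisyLogistic(sim$x, sim$z, theta11 = 1, restarts = 1, seed = 1)
  X <- standardizeFeatures(sim$x)$x
  g <- stats::glm.fit(cbind(1, X), sim$z, family = stats::binomial())
  expect_equal(unname(fit@omega), unname(g$coefficients[-1]), tolerance = 1e-6)
  expect_equal(fit@omega0, unname(-g$coefficients[1]), tolerance = 1e-6)
  expect_equal(fit@theta11, 1)
})

test_that("free-theta fits on noiseless data stay close to the glm solution", {
  sim <- simulateFeatures(2000, c(1.5, -1), omega0 = 0.3, theta11 = 1, seed = 4)
  fit <- fitNoisyLogistic(sim$x, sim$z, restarts = 5, seed = 7)
  X <- standardizeFeatures(sim$x)$x
  g <- stats::glm.fit(cbind(1, X), sim$z, family = stats::binomial())
  glm_ll <- observedLogLik(X, sim$z, g$coefficients[-1], -g$coefficients[1], 1)
  expect_gte(fit@logLik, glm_ll - 1e-6)   # EM cannot do worse than theta = 1
  expect_gte(fit@theta11, 0.9)
  expect_equal(unname(fit@omega), unname(g$coefficients[-1]), tolerance = 0.15)
})

test_that("classification thresholds the marginal score with ties negative", {
  fit <- new("NoisyLabelFit", omega = c(F1 = 1), omega0 = 0, theta11 = 0.5,
             threshold = 0.5, center = c(F1 = 0), scale = c(F1 = 1),
             features = "F1", logLik = 0, trajectory = numeric(),
             responsibilities = numeric(), restartSummary = data.frame(),
             converged = TRUE, iterations = 1L)
  x <- matrix(c(-1, 0, 3), ncol = 1, dimnames = list(NULL, "F1"))
  pred <- classifyPatterns(fit, x)
  expect_equal(pred$score, 0.5 * stats::plogis(c(-1, 0, 3)))
  # theta11 <= T: nothing can be classified functional
  expect_false(any(pred$predicted))
  # noiseless limit reduces to thresholding p(y=1|x) at T
  fit@theta11 <- 1
  pred1 <- classifyPatterns(fit, x)
  expect_equal(pred1$predicted, stats::plogis(c(-1, 0, 3)) > 0.5)
  # a tie with the threshold is non-functional
  x0 <- matrix(0, 1, 1, dimnames = list(NULL, "F1"))  # p = 0.5 = T
  expect_false(classifyPatterns(fit, x0)$predicted)
  # conditional quantity ignores theta11
  fit@theta11 <- 0.2
  expect_equal(classifyPatterns(fit, x, quantity = "conditional")$score,
               stats::plogis(c(-1, 0, 3)))
})

test_that("P10 follows its closed form", {
  fit <- new("NoisyLabelFit", omega = c(F1 = 1), omega0 = 0, theta11 = 1,
             threshold = 0.5, center = c(F1 = 0), scale = c(F1 = 1),
             features = "F1", logLik = 0, trajectory = numeric(),
             responsibilities = numeric(), restartSummary = data.frame(),
             converged = TRUE, iterations = 1L)
  x <- matrix(c(log(4), -1), ncol = 1, dimnames = list(NULL, "F1"))
  z <- c(0L, 0L)
  expect_equal(estimateP10(fit, x, z), 0)       # complete labels
  fit@theta11 <- 0
  expect_equal(estimateP10(fit, x, z), mean(stats::plogis(c(log(4), -1))))
  fit@theta11 <- 0.25
  expect_equal(estimateP10(fit, x[1, , drop = FALSE], 0L), 0.75,
               tolerance = 1e-12)
  expect_error(estimateP10(fit, x, c(1L, 1L)), "z = 0")
})

test_that("restarts converge to the same solution on well-separated data", {
  sim <- simulateFeatures(800, c(2.5), omega0 = 0, theta11 = 0.5, seed = 21)
  fit <- fitNoisyLogistic(sim$x, sim$z, restarts = 10, seed = 2)
  rs <- fit@restartSummary
  expect_equal(rs$parameter, c("omega0", "F1", "theta11"))
  expect_lt(rs$cv[rs$parameter == "theta11"], 0.05)
  expect_true(all(rs$sd >= 0))
})

test_that("models survive a JSON round trip", {
  sim <- simulateFeatures(120, c(1, -1), theta11 = 0.5, seed = 3)
  fit <- fitNoisyLogistic(sim$x, sim$z, restarts = 2, seed = 3)
  f <- tempfile(fileext = ".json")
  writeNoisyModel(fit, f)
  back <- readNoisyModel(f)
  expect_equal(back@omega, fit@omega)
  expect_equal(back@omega0, fit@omega0)
  expect_equal(back@theta11, fit@theta11)
  x <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("F1", "F2")))
  expect_equal(classifyPatterns(back, x), classifyPatterns(fit, x))
})

test_that("partial patterns are scored but excluded from training", {
  sim <- simulateFeatures(300, c(2, -1), theta11 = 0.5, seed = 6)
  ft <- as.data.frame(sim$x)
  rownames(ft) <- sprintf("UP%04d", seq_len(nrow(ft)))
  lab <- ifelse(sim$z == 1, "functional", "non-functional")
  lab[1:20] <- "partial"
  names(lab) <- rownames(ft)
  res <- trainPatternClassifier(ft, lab, restarts = 2, seed = 3)
  expect_equal(nrow(res$predictions), nrow(ft))          # partials scored
  expect_true(all(res$predictions$label[1:20] == "partial"))
  keep <- lab != "partial"
  manual <- fitNoisyLogistic(ft[keep, ], as.integer(lab[keep] == "functional"),
                             restarts = 2, seed = 3)
  expect_equal(res$fit@omega, manual@omega)              # trained without them
  expect_equal(res$fit@theta11, manual@theta11)
})
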