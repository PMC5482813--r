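# --- internal parameterisation -------------------------------------------
# Internally the linear predictor is eta = b0 + X w with b0 = -omega0, so the
# exported offset follows the convention p = 1/(1 + exp(-(w'x) + omega0)):
# omega0 enters the exponent with a PLUS sign. All user-facing values use
# omega0; only `beta` vectors (c(b0, w)) are internal.

featureInput <- function(x) {
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  if (is.null(colnames(m)) && ncol(m) > 0)
    colnames(m) <- paste0("F", seq_len(ncol(m)))
  m
}

#' Probability that a pattern is functional given its features
#'
#' The logistic model `p(y=1|x) = 1 / (1 + exp(-(omega' x) + omega0))`.
#' Note the sign convention: the offset `omega0` is *added* inside the
#' exponent, so larger `omega0` lowers the probability.
#'
#' @param x numeric feature vector, or matrix with one row per pattern.
#' @param omega feature weights.
#' @param omega0 scalar offset.
#' @return probabilities in (0, 1), numerically stable for extreme arguments.
#' @export
probFunctional <- function(x, omega, omega0) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != length(omega)) stop("feature/weight dimension mismatch")
  eta <- if (length(omega)) drop(as.matrix(x) %*% omega) - omega0 else
    rep(-omega0, nrow(x))
  stats::plogis(eta)
}

# log p1 and log(1 - theta11 * p1), stable
obsTerms <- function(eta, theta11) {
  logp1 <- stats::plogis(eta, log.p = TRUE)
  p1 <- stats::plogis(eta)
  list(logp1 = logp1, log_not = log1p(-theta11 * p1), p1 = p1)
}

#' Observed-data log-likelihood of the noisy-label model
#'
#' `sum_t log sum_i theta(i, z_t) p(y_t = i | x_t)` with the one-sided noise
#' structure `theta01 = 0`, `theta00 = 1`, `theta10 = 1 - theta11`. The
#' degenerate case `theta11 = 0` with an observed `z = 1` yields `-Inf`
#' rather than an error.
#'
#' @param x feature matrix (patterns x features).
#' @param z observed binary labels.
#' @param omega,omega0 logistic parameters (see [probFunctional()]).
#' @param theta11 label-completeness parameter in \[0, 1\].
#' @param weights optional per-pattern weights.
#' @return log-likelihood in nats (<= 0 for unit weights).
#' @export
observedLogLik <- function(x, z, omega, omega0, theta11, weights = NULL) {
  x <- featureInput(x)
  if (is.null(weights)) weights <- rep(1, nrow(x))
  eta <- if (length(omega)) drop(x %*% omega) - omega0 else rep(-omega0, nrow(x))
  tm <- obsTerms(eta, theta11)
  term <- ifelse(z == 1L, log(theta11) + tm$logp1, tm$log_not)
  sum(weights * term)
}

#' E-step responsibilities
#'
#' `c_t = p(y_t = 1 | z_t, x_t)`. An observed functional label forces
#' certainty (`c = 1`, since non-functional patterns are never mislabeled
#' functional); for `z = 0`,
#' `c = (1 - theta11) p1 / ((1 - p1) + (1 - theta11) p1)`.
#'
#' @inheritParams observedLogLik
#' @return numeric vector of responsibilities in \[0, 1\].
#' @export
eStep <- function(x, z, omega, omega0, theta11) {
  x <- featureInput(x)
  if (any(z == 1L) && theta11 == 0)
    stop("degenerate labels: theta11 = 0 but an observed label is 1")
  if (theta11 == 1) return(as.numeric(z == 1L))
  p1 <- probFunctional(x, omega, omega0)
  ifelse(z == 1L, 1, (1 - theta11) * p1 / (1 - theta11 * p1))
}

#' M-step update of theta11
#'
#' `theta11 = sum_t w_t c_t 1{z_t = 1} / sum_t w_t c_t`.
#'
#' @param c1 E-step responsibilities.
#' @param z observed labels.
#' @param weights optional weights.
#' @export
mStepTheta <- function(c1, z, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(c1))
  sum(weights * c1 * (z == 1L)) / sum(weights * c1)
}

# maximize the weighted logistic objective
#   L2(beta) = sum_t w_t [ c_t log p_t + (1 - c_t) log(1 - p_t) ]
# by Newton with step-halving; gradient ascent fallback when the Hessian is
# singular. X1 includes the intercept column.
weightedLogistic <- function(X1, c1, w, beta, method = "newton", tau = 0.5,
                             maxit = 100L) {
  L2 <- function(b) {
    eta <- drop(X1 %*% b)
    sum(w * (c1 * stats::plogis(eta, log.p = TRUE) +
             (1 - c1) * stats::plogis(-eta, log.p = TRUE)))
  }
  cur <- L2(beta)
  for (it in seq_len(maxit)) {
    p <- stats::plogis(drop(X1 %*% beta))
    grad <- drop(crossprod(X1, w * (c1 - p)))
    if (max(abs(grad)) < 1e-10) break
    step <- NULL
    if (method == "newton") {
      wt <- w * p * (1 - p)
      H <- crossprod(X1, X1 * wt)
      step <- tryCatch(solve(H + diag(1e-10, ncol(X1)), grad),
                       error = function(e) NULL)
    }
    if (is.null(step)) step <- tau * grad  # gradient ascent (singular Hessian)
    new_beta <- beta + step
    new_val <- L2(new_beta)
    halvings <- 0L
    while (new_val < cur && halvings < 40L) {  # concave objective: halve back
      step <- step / 2
      new_beta <- beta + step
      new_val <- L2(new_beta)
      halvings <- halvings + 1L
    }
    if (new_val < cur) break
    if (new_val - cur < 1e-12 * (abs(cur) + 1)) { beta <- new_beta; cur <- new_val; break }
    beta <- new_beta; cur <- new_val
  }
  list(beta = beta, value = cur)
}

#' Fit the noisy-label logistic model by EM
#'
#' Alternates the E-step (responsibilities `c_t`) with the M-step (closed-form
#' `theta11` update and a weighted logistic fit for `omega`) until the
#' observed-data log-likelihood improves by less than `tol`. Because the
#' likelihood is multimodal, the fit is restarted from random `theta11`
#' values (uniform in (0.05, 0.95)); `omega` starts at a plain logistic
#' regression of `z` on `x` in the first restart and at jittered versions of
#' it afterwards (varying only `theta11` cannot leave a basin in `omega`).
#' The best-likelihood restart is returned together with per-parameter mean,
#' SD and coefficient of variation across restarts.
#'
#' @param x feature matrix or data.frame (patterns x features). Standardized
#'   internally by default (binary columns left as 0/1).
#' @param z observed binary labels (1 = labeled functional).
#' @param weights optional per-pattern weights (e.g. multiplicities); the
#'   default trains on unique patterns unweighted.
#' @param theta11 `NULL` to estimate; a number in \[0, 1\] to hold it fixed
#'   (with `theta11 = 1` the fit reduces exactly to plain logistic
#'   regression).
#' @param restarts number of random restarts (>= 1).
#' @param seed optional integer seed controlling the restart draws.
#' @param tol absolute convergence tolerance on the observed log-likelihood.
#' @param maxIter maximum EM iterations per cycle (the observed likelihood
#'   has a flat ridge between `theta11` and the offset along which plain EM
#'   moves slowly; EM cycles therefore alternate with a safeguarded
#'   quasi-Newton polish of the observed likelihood, accepted only when it
#'   improves it, up to five cycles).
#' @param threshold classification threshold T stored with the model.
#' @param standardize standardize features before fitting.
#' @param mStepMethod `"newton"` (default; step-halved Newton with gradient
#'   fallback) or `"gradient"` (plain gradient ascent with rate `tau`).
#' @param tau gradient-ascent learning rate.
#' @return a [NoisyLabelFit-class].
#' @export
fitNoisyLogistic <- function(x, z, weights = NULL, theta11 = NULL,
                             restarts = 100L, seed = NULL, tol = 1e-8,
                             maxIter = 500L, threshold = 0.5,
                             standardize = TRUE,
                             mStepMethod = c("newton", "gradient"), tau = 0.5) {
  mStepMethod <- match.arg(mStepMethod)
  x <- featureInput(x)
  z <- as.integer(z)
  stopifnot(nrow(x) == length(z), all(z %in% 0:1), restarts >= 1L)
  if (nrow(x) < 2L || length(unique(z)) < 2L)
    stop("training needs at least two patterns with both label values present")
  if (is.null(weights)) weights <- rep(1, nrow(x))
  std <- if (standardize) standardizeFeatures(x) else
    list(x = x, center = stats::setNames(rep(0, ncol(x)), colnames(x)),
         scale = stats::setNames(rep(1, ncol(x)), colnames(x)))
  X <- std$x
  X1 <- cbind(`(Intercept)` = 1, X)
  theta_fixed <- !is.null(theta11)
  init_beta <- tryCatch(
    suppressWarnings(stats::glm.fit(X1, z, weights = weights,
                                    family = stats::binomial())$coefficients),
    error = function(e) rep(0, ncol(X1)))
  init_beta[!is.finite(init_beta)] <- 0
  if (!is.null(seed)) set.seed(seed)
  theta_inits <- if (theta_fixed) rep(theta11, restarts) else
    stats::runif(restarts, 0.05, 0.95)
  # restart 1 starts at the plain logistic fit; later restarts jitter the
  # weights as well, since varying only theta11 cannot leave its basin
  beta_inits <- c(list(init_beta),
                  lapply(seq_len(max(restarts - 1L, 0L)), function(r)
                    init_beta + stats::rnorm(length(init_beta))))
  obs_ll <- function(beta, th)
    observedLogLik(X, z, beta[-1L], -beta[1L], th, weights)
  # safeguarded quasi-Newton refinement of the observed likelihood; the
  # one-sided-noise likelihood has a flat ridge between theta11 and the
  # offset along which plain EM moves very slowly, so EM cycles alternate
  # with a polish step that is only accepted when it improves the objective
  polish <- function(beta, th) {
    if (theta_fixed) {
      par0 <- beta
      f <- function(p) -obs_ll(p, th)
    } else {
      par0 <- c(beta, stats::qlogis(min(max(th, 1e-12), 1 - 1e-12)))
      f <- function(p) -obs_ll(p[-length(p)], stats::plogis(p[length(p)]))
    }
    o <- tryCatch(stats::optim(par0, f, method = "BFGS",
                               control = list(maxit = 500, reltol = 1e-14)),
                  error = function(e) NULL)
    if (is.null(o) || -o$value <= obs_ll(beta, th)) return(NULL)
    if (theta_fixed) list(beta = o$par, th = th, ll = -o$value)
    else list(beta = o$par[-length(o$par)],
              th = stats::plogis(o$par[length(o$par)]), ll = -o$value)
  }
  runs <- vector("list", restarts)
  for (r in seq_len(restarts)) {
    beta <- beta_inits[[r]]
    th <- theta_inits[r]
    traj <- obs_ll(beta, th)
    converged <- FALSE
    it_total <- 0L
    for (cycle in 1:5) {
      em_conv <- FALSE
      for (it in seq_len(maxIter)) {
        it_total <- it_total + 1L
        c1 <- eStep(X, z, beta[-1L], -beta[1L], th)
        if (!theta_fixed) th <- mStepTheta(c1, z, weights)
        beta <- weightedLogistic(X1, c1, weights, beta, method = mStepMethod,
                                 tau = tau)$beta
        ll <- obs_ll(beta, th)
        if (ll < traj[length(traj)] - 1e-8)
          warning(sprintf("observed log-likelihood decreased by %.3g at iteration %d",
                          traj[length(traj)] - ll, it_total))
        traj <- c(traj, ll)
        if (abs(ll - traj[length(traj) - 1L]) < tol) { em_conv <- TRUE; break }
      }
      ref <- polish(beta, th)
      if (is.null(ref) || ref$ll - traj[length(traj)] < tol) {
        converged <- em_conv || !is.null(ref)
        if (!is.null(ref)) { beta <- ref$beta; th <- ref$th; traj <- c(traj, ref$ll) }
        break
      }
      beta <- ref$beta; th <- ref$th
      traj <- c(traj, ref$ll)
    }
    runs[[r]] <- list(beta = beta, theta11 = th, logLik = traj[length(traj)],
                      traj = traj, converged = converged, iterations = it_total)
  }
  if (!any(vapply(runs, `[[`, logical(1), "converged")))
    warning("no restart reached the convergence tolerance; returning the best trajectory")
  lls <- vapply(runs, `[[`, numeric(1), "logLik")
  best <- runs[[which.max(lls)]]
  par_mat <- t(vapply(runs, function(r) c(-r$beta[1L], r$beta[-1L], r$theta11),
                      numeric(ncol(X1) + 1L)))
  colnames(par_mat) <- c("omega0", colnames(X), "theta11")
  mu <- colMeans(par_mat); sdv <- apply(par_mat, 2L, stats::sd)
  rs <- data.frame(parameter = colnames(par_mat), mean = mu, sd = sdv,
                   cv = ifelse(mu != 0, sdv / abs(mu), NA_real_),
                   row.names = NULL)
  new("NoisyLabelFit",
      omega = stats::setNames(best$beta[-1L], colnames(X)),
      omega0 = unname(-best$beta[1L]), theta11 = best$theta11,
      threshold = threshold, center = std$center, scale = std$scale,
      features = colnames(X), logLik = best$logLik, trajectory = best$traj,
      responsibilities = eStep(X, z, best$beta[-1L], -best$beta[1L], best$theta11),
      restartSummary = rs, converged = best$converged,
      iterations = as.integer(best$iterations))
}

setMethod("show", "NoisyLabelFit", function(object) {
  cat(sprintf("NoisyLabelFit: %d features; theta11 = %.4f; logLik = %.4f (%d EM iterations%s)\n",
              length(object@omega), object@theta11, object@logLik,
              object@iterations,
              if (object@converged) "" else ", not converged"))
})

# standardized feature matrix for a fitted model
applyStandardization <- function(fit, features) {
  m <- featureInput(features)
  miss <- setdiff(fit@features, colnames(m))
  if (length(miss)) stop("missing features: ", paste(miss, collapse = ", "))
  m <- m[, fit@features, drop = FALSE]
  standardizeFeatures(m, center = fit@center, scale = fit@scale)$x
}

#' Classify patterns with a fitted noisy-label model
#'
#' The default classification quantity is the marginal probability of an
#' observed functional label, `theta11 * p(y=1|x)` (the model's
#' `p(z=1|x)`); set `quantity = "conditional"` to threshold `p(y=1|x)`
#' itself. A pattern is predicted functional iff its score strictly exceeds
#' the threshold (ties are non-functional).
#'
#' @param fit a [NoisyLabelFit-class].
#' @param features raw (unstandardized) feature table; standardization stored
#'   in the fit is applied.
#' @param quantity `"marginal"` (default) or `"conditional"`.
#' @param threshold classification threshold; defaults to the fit's T.
#' @return data.frame: `pattern`, `p_functional` (`p(y=1|x)`), `score`,
#'   `predicted` (logical).
#' @export
classifyPatterns <- function(fit, features,
                             quantity = c("marginal", "conditional"),
                             threshold = NULL) {
  quantity <- match.arg(quantity)
  if (is.null(threshold)) threshold <- fit@threshold
  X <- applyStandardization(fit, features)
  p1 <- probFunctional(X, fit@omega, fit@omega0)
  score <- if (quantity == "marginal") fit@theta11 * p1 else p1
  data.frame(pattern = if (!is.null(rownames(X))) rownames(X)
             else seq_len(nrow(X)),
             p_functional = p1, score = score,
             predicted = score > threshold,
             stringsAsFactors = FALSE)
}

#' Probability that an unlabeled pattern is truly functional
#'
#' `P10 = mean over {t : z_t = 0} of p(y_t = 1 | z_t = 0, x_t)
#'  = (1 - theta11) p1 / (1 - theta11 p1)` averaged over the patterns labeled
#' non-functional: the estimated fraction of functional patterns among those
#' not labeled as such.
#'
#' @param fit a [NoisyLabelFit-class].
#' @param features raw feature table used at training.
#' @param z observed labels matching `features` rows.
#' @return P10 in \[0, 1\].
#' @export
estimateP10 <- function(fit, features, z) {
  if (!any(z == 0L)) stop("P10 requires at least one pattern with z = 0")
  X <- applyStandardization(fit, features)
  p1 <- probFunctional(X, fit@omega, fit@omega0)[z == 0L]
  mean((1 - fit@theta11) * p1 / (1 - fit@theta11 * p1))
}

#' Train the pattern classifier from a labeled pattern set
#'
#' Maps pattern labels to training labels (`z = 1` for `functional`, `z = 0`
#' for `non-functional`), excludes `partial` patterns from training, fits the
#' noisy-label model, and scores every pattern (including the partial ones).
#'
#' @param features 13-feature table from [buildFeatureTable()].
#' @param labels character labels per pattern (see [patternLabels()]), or a
#'   [PatternSet-class].
#' @param weightByMultiplicity weight training patterns by their occurrence
#'   multiplicity (requires a [PatternSet-class] as `labels`); the default
#'   trains on unique patterns unweighted.
#' @param ... passed to [fitNoisyLogistic()].
#' @return list with `fit` (a [NoisyLabelFit-class]), `predictions`
#'   (data.frame over all patterns, with `label`), and `p10`.
#' @export
trainPatternClassifier <- function(features, labels,
                                   weightByMultiplicity = FALSE, ...) {
  w <- NULL
  if (is(labels, "PatternSet")) {
    if (weightByMultiplicity)
      w <- as.numeric(multiplicity(labels)[rownames(features)])
    labels <- patternLabels(labels)
  } else if (weightByMultiplicity) {
    stop("multiplicity weighting needs a PatternSet as 'labels'")
  }
  labels <- labels[rownames(features)]
  train <- labels != "partial"
  z <- as.integer(labels[train] == "functional")
  fit <- fitNoisyLogistic(features[train, , drop = FALSE], z,
                          weights = w[train], ...)
  pred <- classifyPatterns(fit, features)
  pred$label <- unname(labels)
  list(fit = fit,
       predictions = pred,
       p10 = estimateP10(fit, features[train, , drop = FALSE], z))
}

#' Serialize / restore a fitted model as JSON
#' @param fit a [NoisyLabelFit-class].
#' @param file path to the JSON file.
#' @export
writeNoisyModel <- function(fit, file) {
  jsonlite::write_json(
    list(features = fit@features, omega = as.list(fit@omega),
         omega0 = fit@omega0, theta11 = fit@theta11,
         threshold = fit@threshold,
         center = as.list(fit@center), scale = as.list(fit@scale),
         logLik = fit@logLik, converged = fit@converged,
         restartSummary = fit@restartSummary),
    file, auto_unbox = TRUE, digits = NA)
}

#' @rdname writeNoisyModel
#' @export
readNoisyModel <- function(file) {
  j <- jsonlite::read_json(file, simplifyVector = TRUE)
  new("NoisyLabelFit",
      omega = unlist(j$omega), omega0 = j$omega0, theta11 = j$theta11,
      threshold = j$threshold, center = unlist(j$center),
      scale = unlist(j$scale), features = j$features,
      logLik = j$logLik, trajectory = numeric(), responsibilities = numeric(),
      restartSummary = as.data.frame(j$restartSummary),
      converged = isTRUE(j$converged), iterations = NA_integer_)
}
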