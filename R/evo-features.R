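# canonical order of the 13 pattern-characterizing features
FEATURE_ORDER <- c("LOG_LIKE", "ONES_KNOWN", "SANKOFF_G1L3", "SANKOFF_G3L1",
                   "IN_AMPHIBIAN", "IN_FISH", "IN_BIRD", "IN_FUNGI",
                   "IN_PLANT", "IN_PROTIST", "LCA_AGE",
                   "MED_POSITION", "MED_REL_POSITION")

# coerce a pattern input (PatternSet, named vector, or matrix) to an integer
# matrix patterns x species
patternInput <- function(x, tree = NULL) {
  if (is(x, "PatternSet")) x <- x@patterns
  if (is.null(dim(x))) {
    nm <- names(x)
    x <- matrix(as.integer(x), nrow = 1L)
    colnames(x) <- nm
  }
  x <- as.matrix(x)
  if (is.null(colnames(x))) {
    if (!is.null(tree) && ncol(x) == length(leafNames(tree)))
      colnames(x) <- leafNames(tree)
    else stop("pattern species names are required")
  }
  if (!is.null(tree)) {
    unknown <- setdiff(colnames(x), leafNames(tree))
    if (length(unknown))
      stop("unknown species: ", paste(unknown, collapse = ", "))
  }
  storage.mode(x) <- "integer"
  x
}

# tip partial matrices for a pattern matrix on a tree; species of the tree
# not covered by the pattern are treated as missing (code 2)
tipStates <- function(v, tree) {
  tips <- leafNames(tree)
  m <- matrix(2L, nrow = nrow(v), ncol = length(tips),
              dimnames = list(rownames(v), tips))
  m[, colnames(v)] <- v
  m
}

#' Sankoff parsimony cost of patterns under asymmetric gain/loss pricing
#'
#' Minimum total cost over all ancestral state assignments of explaining the
#' tip pattern, with cost `gain` for a 0 to 1 change, `loss` for 1 to 0, zero
#' for no change, and no cost on the root state. Missing tips (value 2) admit
#' either state at zero cost. Computed by the Sankoff dynamic program in a
#' single post-order pass, vectorised over patterns.
#'
#' @param x a [PatternSet-class], a named 0/1/2 vector, or a matrix
#'   (patterns x species).
#' @param tree a [DatedTree-class].
#' @param gain,loss positive per-event costs.
#' @return numeric vector of minimal costs, one per pattern.
#' @export
sankoffCost <- function(x, tree, gain = 1, loss = 3) {
  stopifnot(is(tree, "DatedTree"), gain > 0, loss > 0)
  v <- tipStates(patternInput(x, tree), tree)
  tr <- stats::reorder(tree@tree, "postorder")
  ntip <- length(tr$tip.label)
  nn <- ntip + tr$Nnode
  npat <- nrow(v)
  tip_v <- v[, tr$tip.label, drop = FALSE]
  S0 <- matrix(0, npat, nn); S1 <- matrix(0, npat, nn)
  S0[, seq_len(ntip)] <- ifelse(tip_v == 1L, Inf, 0)
  S1[, seq_len(ntip)] <- ifelse(tip_v == 0L, Inf, 0)
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    S0[, par] <- S0[, par] + pmin(S0[, ch], gain + S1[, ch])
    S1[, par] <- S1[, par] + pmin(loss + S0[, ch], S1[, ch])
  }
  root <- ntip + 1L
  stats::setNames(pmin(S0[, root], S1[, root]), rownames(v))
}

#' Dollo parsimony age of a pattern's origin
#'
#' Under Dollo parsimony an intron arises once; the origin is dated at the
#' most recent common ancestor of all species carrying the intron (value 1).
#'
#' @inheritParams sankoffCost
#' @return numeric vector of ages in MY.
#' @export
dolloLcaAge <- function(x, tree) {
  v <- patternInput(x, tree)
  apply(v, 1L, function(row) {
    sp <- colnames(v)[row == 1L]
    if (!length(sp)) stop("pattern has no species with value 1")
    mrcaAge(tree, sp)
  })
}

#' Presence-ratio and clade-presence features
#'
#' `ONES_KNOWN` is the fraction of 1's among non-missing entries; each
#' `IN_<GROUP>` indicator is 1 iff at least one member of the group carries
#' the intron.
#'
#' @param x pattern input as in [sankoffCost()].
#' @param clades named list of species groups (see [exampleClades()]).
#' @return data.frame with `ONES_KNOWN` and one `IN_*` column per group.
#' @export
cladeFeatures <- function(x, clades) {
  v <- patternInput(x)
  known <- rowSums(v != 2L)
  if (any(known == 0L))
    stop("pattern with all entries missing: ONES_KNOWN undefined")
  out <- data.frame(ONES_KNOWN = rowSums(v == 1L) / known)
  for (g in names(clades)) {
    members <- clades[[g]]
    miss <- setdiff(members, colnames(v))
    if (length(miss))
      stop(sprintf("clade '%s' members not among pattern species: %s",
                   g, paste(miss, collapse = ", ")))
    out[[paste0("IN_", toupper(g))]] <-
      as.integer(rowSums(v[, members, drop = FALSE] == 1L) > 0L)
  }
  rownames(out) <- rownames(v)
  out
}

#' Construct a gain/loss model by hand
#' @param gain,loss CTMC rates in events per MY.
#' @param pi1 root probability of presence; defaults to the stationary value
#'   `gain / (gain + loss)`.
#' @return a [GainLossModel-class].
#' @export
gainLossModel <- function(gain, loss, pi1 = NULL) {
  if (is.null(pi1))
    pi1 <- if (gain + loss > 0) gain / (gain + loss) else 0.5
  new("GainLossModel", gain = gain, loss = loss, pi1 = pi1,
      logLik = NA_real_, converged = NA)
}

setMethod("show", "GainLossModel", function(object) {
  cat(sprintf("GainLossModel: gain %.4g, loss %.4g /MY; pi1 %.3f; logLik %s\n",
              object@gain, object@loss, object@pi1, format(object@logLik)))
})

# 2-state CTMC transition probabilities over time t:
# returns c(p00, p01, p10, p11)
ctmcTransition <- function(gain, loss, t) {
  r <- gain + loss
  if (r == 0 || t == 0) return(c(1, 0, 0, 1))
  e <- exp(-r * t)
  c((loss + gain * e) / r, gain * (1 - e) / r,
    loss * (1 - e) / r, (gain + loss * e) / r)
}

#' Log-likelihood of patterns under a gain/loss model
#'
#' Felsenstein pruning on the dated tree under the homogeneous two-state
#' CTMC; missing tips (value 2) contribute likelihood 1 for both states.
#' Vectorised over patterns, with per-node rescaling for numerical stability.
#'
#' @inheritParams sankoffCost
#' @param model a [GainLossModel-class].
#' @return numeric vector of log-likelihoods (nats, all <= 0).
#' @export
patternLogLik <- function(x, tree, model) {
  stopifnot(is(tree, "DatedTree"), is(model, "GainLossModel"))
  v <- tipStates(patternInput(x, tree), tree)
  tr <- stats::reorder(tree@tree, "postorder")
  ntip <- length(tr$tip.label)
  nn <- ntip + tr$Nnode
  npat <- nrow(v)
  tip_v <- v[, tr$tip.label, drop = FALSE]
  L0 <- matrix(1, npat, nn); L1 <- matrix(1, npat, nn)
  L0[, seq_len(ntip)] <- ifelse(tip_v == 1L, 0, 1)
  L1[, seq_len(ntip)] <- ifelse(tip_v == 0L, 0, 1)
  logS <- matrix(0, npat, nn)
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    P <- ctmcTransition(model@gain, model@loss, tr$edge.length[e])
    c0 <- P[1] * L0[, ch] + P[2] * L1[, ch]
    c1 <- P[3] * L0[, ch] + P[4] * L1[, ch]
    L0[, par] <- L0[, par] * c0
    L1[, par] <- L1[, par] * c1
    logS[, par] <- logS[, par] + logS[, ch]
    m <- pmax(L0[, par], L1[, par])
    m[m == 0] <- 1
    L0[, par] <- L0[, par] / m; L1[, par] <- L1[, par] / m
    logS[, par] <- logS[, par] + log(m)
  }
  root <- ntip + 1L
  ll <- log((1 - model@pi1) * L0[, root] + model@pi1 * L1[, root]) + logS[, root]
  stats::setNames(ll, rownames(v))
}

#' Fit the gain/loss model to a pattern collection by maximum likelihood
#'
#' Maximises the (multiplicity-weighted) sum of pattern log-likelihoods over
#' the gain and loss rates, with the root distribution tied to the chain's
#' stationary distribution, by L-BFGS-B on log-rates from several starting
#' points.
#'
#' @inheritParams sankoffCost
#' @param weightByMultiplicity weight each unique pattern by its number of
#'   occurrences (the likelihood of the observed column data); disable to
#'   weight unique patterns equally.
#' @param weights optional explicit per-pattern weights (overrides
#'   `weightByMultiplicity`).
#' @return a fitted [GainLossModel-class].
#' @export
fitGainLoss <- function(x, tree, weightByMultiplicity = TRUE, weights = NULL) {
  v <- patternInput(x, tree)
  if (is.null(weights)) {
    weights <- if (weightByMultiplicity && is(x, "PatternSet"))
      as.numeric(x@multiplicity) else rep(1, nrow(v))
  }
  stopifnot(length(weights) == nrow(v))
  obj <- function(par) {
    m <- gainLossModel(exp(par[1]), exp(par[2]))
    -sum(weights * patternLogLik(v, tree, m))
  }
  s <- log(1 / rootAge(tree))
  starts <- list(c(s, s), c(s - 2, s + 1), c(s + 1, s - 2), c(s + 2, s + 2))
  fits <- lapply(starts, function(p0)
    tryCatch(stats::optim(p0, obj, method = "L-BFGS-B",
                          lower = c(-25, -25), upper = c(5, 5)),
             error = function(e) NULL))
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok))
    stop("gain/loss optimizer failed from every starting point")
  best <- fits[ok][[which.min(vapply(fits[ok], `[[`, numeric(1), "value"))]]
  m <- gainLossModel(exp(best$par[1]), exp(best$par[2]))
  m@logLik <- -best$value
  m@converged <- best$convergence == 0L
  if (!m@converged)
    warning("gain/loss optimizer did not report convergence; returning best solution found")
  m
}

#' Median CDS-position features of each unique pattern
#'
#' `MED_POSITION` is the median over a pattern's occurrences of the 1-based
#' nucleotide distance from the CDS start to the exon-exon junction on the
#' human transcript; `MED_REL_POSITION` divides each distance by that
#' occurrence's CDS length before taking the median. The median of an even
#' number of occurrences is the mean of the two middle values.
#'
#' @param x a [PatternSet-class].
#' @return data.frame with columns `MED_POSITION`, `MED_REL_POSITION`.
#' @export
positionFeatures <- function(x) {
  stopifnot(is(x, "PatternSet"))
  occ <- x@occurrences
  bad <- which(is.na(occ$position) | is.na(occ$cds_length))
  if (length(bad))
    stop(sprintf("occurrence %s:%d of pattern %s lacks position metadata",
                 occ$set_id[bad[1]], occ$column[bad[1]], occ$pattern[bad[1]]))
  ids <- rownames(x@patterns)
  f <- factor(occ$pattern, levels = ids)
  data.frame(
    MED_POSITION = as.numeric(tapply(occ$position, f, stats::median)),
    MED_REL_POSITION = as.numeric(tapply(occ$position / occ$cds_length, f,
                                         stats::median)),
    row.names = ids)
}

#' Assemble the 13-feature table for a pattern set
#'
#' One row per unique pattern with the 13 pattern-characterizing features:
#' `LOG_LIKE` (pattern log-likelihood under `model`), `ONES_KNOWN`,
#' `SANKOFF_G1L3` (loss costs three times gain), `SANKOFF_G3L1` (gain costs
#' three times loss), the six clade-presence indicators, `LCA_AGE` (Dollo
#' origin age), `MED_POSITION` and `MED_REL_POSITION`.
#'
#' @param x a [PatternSet-class].
#' @param tree a [DatedTree-class].
#' @param clades named list of clade memberships.
#' @param model a [GainLossModel-class]; fitted on `x` via [fitGainLoss()]
#'   when `NULL`.
#' @return data.frame (patterns x features), deterministic given its inputs.
#' @export
buildFeatureTable <- function(x, tree, clades = exampleClades(), model = NULL) {
  stopifnot(is(x, "PatternSet"))
  if (is.null(model)) model <- fitGainLoss(x, tree)
  out <- cbind(
    data.frame(LOG_LIKE = as.numeric(patternLogLik(x, tree, model)),
               row.names = rownames(x@patterns)),
    cladeFeatures(x, clades),
    data.frame(SANKOFF_G1L3 = as.numeric(sankoffCost(x, tree, gain = 1, loss = 3)),
               SANKOFF_G3L1 = as.numeric(sankoffCost(x, tree, gain = 3, loss = 1)),
               LCA_AGE = as.numeric(dolloLcaAge(x, tree))),
    positionFeatures(x))
  ord <- intersect(FEATURE_ORDER, names(out))
  out[, c(ord, setdiff(names(out), ord)), drop = FALSE]
}

#' Standardize a feature table
#'
#' Continuous features are z-scored; binary (0/1) features are left as-is
#' (center 0, scale 1). Standardization parameters are returned so the same
#' transform can be applied at prediction time.
#'
#' @param x feature data.frame or matrix.
#' @param center,scale optional previously computed parameters to apply.
#' @return list with `x` (standardized matrix), `center`, `scale`.
#' @export
standardizeFeatures <- function(x, center = NULL, scale = NULL) {
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  if (is.null(center)) {
    binary <- apply(m, 2L, function(col) all(col %in% c(0, 1)))
    center <- ifelse(binary, 0, colMeans(m))
    scale <- ifelse(binary, 1, apply(m, 2L, stats::sd))
    scale[scale == 0 | is.na(scale)] <- 1
    names(center) <- names(scale) <- colnames(m)
  }
  list(x = sweep(sweep(m, 2L, center[colnames(m)]), 2L, scale[colnames(m)], "/"),
       center = center, scale = scale)
}

#' Write a feature table / gain-loss model to disk
#' @param x feature data.frame.
#' @param file output path.
#' @export
writeFeatureTable <- function(x, file) {
  utils::write.table(cbind(pattern = rownames(x), x), file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(file) {
  d <- utils::read.delim(file)
  rownames(d) <- d$pattern
  d$pattern <- NULL
  d
}

#' @rdname writeFeatureTable
#' @param model a [GainLossModel-class].
#' @export
writeGainLossModel <- function(model, file) {
  jsonlite::write_json(list(gain = model@gain, loss = model@loss,
                            pi1 = model@pi1, logLik = model@logLik),
                       file, auto_unbox = TRUE, digits = NA)
}

#' @rdname writeFeatureTable
#' @export
readGainLossModel <- function(file) {
  j <- jsonlite::read_json(file, simplifyVector = TRUE)
  m <- gainLossModel(j$gain, j$loss, j$pi1)
  m@logLik <- if (is.null(j$logLik)) NA_real_ else j$logLik
  m
}
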