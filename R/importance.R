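# equal-frequency discretization of a continuous feature (binary features,
# i.e. <= 2 distinct values, are used as-is)
discretizeFeature <- function(x, bins = 10L) {
  u <- unique(x)
  if (length(u) <= 2L) return(as.integer(factor(x)))
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1L),
                               names = FALSE, type = 7))
  if (length(br) < 2L) return(rep(1L, length(x)))
  as.integer(cut(x, breaks = br, include.lowest = TRUE))
}

#' Mutual information between a feature and the predicted labels
#'
#' Plug-in estimate `I(X;Y) = sum P(x,y) log2 [P(x,y) / (P(x) P(y))]` in
#' bits, with `0 log 0 := 0`. Continuous features are discretized into
#' `bins` equal-frequency bins first; binary features are used as-is.
#'
#' @param x feature values.
#' @param y binary labels of equal length.
#' @param bins number of equal-frequency bins for continuous features.
#' @return mutual information in bits (>= 0).
#' @export
mutualInformation <- function(x, y, bins = 10L) {
  stopifnot(length(x) == length(y))
  if (length(unique(y)) < 2L) {
    warning("label vector is constant; mutual information is 0")
    return(0)
  }
  xb <- discretizeFeature(x, bins)
  tab <- table(xb, y)
  pxy <- tab / sum(tab)
  px <- rowSums(pxy); py <- colSums(pxy)
  terms <- pxy * log2(pxy / outer(px, py))
  sum(terms[pxy > 0])
}

#' @describeIn mutualInformation mutual information of every feature column
#'   with the predicted labels, sorted decreasing.
#' @param features feature table.
#' @export
featureMutualInformation <- function(features, y, bins = 10L) {
  mi <- vapply(as.data.frame(features), mutualInformation, numeric(1),
               y = y, bins = bins)
  sort(mi, decreasing = TRUE)
}

# fit on a feature subset (possibly empty -> intercept-only model) and return
# the marginal functional score theta11 * p(y=1|x) on the training patterns
subsetScores <- function(features, z, subset, restarts, seed, ...) {
  if (length(subset) == 0L) {
    # intercept-only: EM on a single constant pseudo-feature of zeros
    X <- matrix(0, nrow(features), 1L, dimnames = list(rownames(features), "NONE"))
    fit <- fitNoisyLogistic(X, z, restarts = restarts, seed = seed,
                            standardize = FALSE, ...)
    return(classifyPatterns(fit, X)$score)
  }
  fit <- fitNoisyLogistic(features[, subset, drop = FALSE], z,
                          restarts = restarts, seed = seed, ...)
  classifyPatterns(fit, features[, subset, drop = FALSE])$score
}

#' Performance distance of a feature subset
#'
#' Retrains the noisy-label model on the subset alone (same seed and
#' initialisation scheme as the reference fit) and returns
#' `Performance(F) = sum_p (Pr_F(p) - Pr_0(p))^2`, the squared distance
#' between the subset model's functional scores and the full-model scores
#' `Pr_0`. Larger distance = worse agreement with the full model.
#'
#' @param features full feature table (training patterns only).
#' @param z observed binary labels.
#' @param subset character vector of feature names (may be empty).
#' @param reference full-model scores `Pr_0`; computed from a full-feature
#'   fit when `NULL`.
#' @param restarts restarts used inside the battery (default 10).
#' @param seed seed shared by all retrainings.
#' @param ... passed to [fitNoisyLogistic()].
#' @return non-negative distance.
#' @export
subsetPerformance <- function(features, z, subset, reference = NULL,
                              restarts = 10L, seed = 1L, ...) {
  features <- featureInput(features)
  if (is.null(reference))
    reference <- subsetScores(features, z, colnames(features), restarts, seed, ...)
  pr <- subsetScores(features, z, subset, restarts, seed, ...)
  sum((pr - reference)^2)
}

#' Leave-one-out and single-feature importance
#'
#' `leaveOneOutImportance` retrains the model 13 times, each time with one
#' feature left out; a large distance from the full-model predictions marks
#' an important feature. `singleFeatureImportance` retrains on each feature
#' alone; a small distance marks a feature that carries much of the signal by
#' itself.
#'
#' @inheritParams subsetPerformance
#' @return named numeric vector of distances (sorted decreasing for
#'   leave-one-out, increasing for single-feature).
#' @export
leaveOneOutImportance <- function(features, z, restarts = 10L, seed = 1L, ...) {
  features <- featureInput(features)
  fn <- colnames(features)
  ref <- subsetScores(features, z, fn, restarts, seed, ...)
  d <- vapply(fn, function(f)
    subsetPerformance(features, z, setdiff(fn, f), ref, restarts, seed, ...),
    numeric(1))
  sort(d, decreasing = TRUE)
}

#' @rdname leaveOneOutImportance
#' @export
singleFeatureImportance <- function(features, z, restarts = 10L, seed = 1L, ...) {
  features <- featureInput(features)
  fn <- colnames(features)
  ref <- subsetScores(features, z, fn, restarts, seed, ...)
  d <- vapply(fn, function(f)
    subsetPerformance(features, z, f, ref, restarts, seed, ...), numeric(1))
  sort(d, decreasing = FALSE)
}

#' Sequential "remove two, add one" feature selection
#'
#' In each iteration the pair of kept features whose joint removal changes
#' the performance distance least is removed, then the single feature from
#' the whole rejected set whose return improves performance most is re-added
#' (it may have been rejected in an earlier iteration) - a net loss of one
#' feature per iteration, down to a single surviving feature. With 13
#' features the survivor emerges after 12 iterations.
#'
#' @inheritParams subsetPerformance
#' @return list with `survivor`, `history` (data.frame: iteration, removed
#'   pair, re-added feature, performance of the kept set), and
#'   `eliminationOrder` (features in the order they left the kept set for
#'   good).
#' @export
sequentialSelection <- function(features, z, restarts = 10L, seed = 1L, ...) {
  features <- featureInput(features)
  fn <- colnames(features)
  if (length(fn) < 3L) stop("sequential selection needs at least 3 features")
  ref <- subsetScores(features, z, fn, restarts, seed, ...)
  cache <- new.env(parent = emptyenv())
  perf <- function(sub) {
    key <- paste0("S:", paste(sort(sub), collapse = "|"))
    if (is.null(cache[[key]]))
      cache[[key]] <- subsetPerformance(features, z, sub, ref, restarts, seed, ...)
    cache[[key]]
  }
  kept <- fn; rejected <- character()
  hist <- list()
  it <- 0L
  while (length(kept) > 1L) {
    it <- it + 1L
    pairs <- utils::combn(kept, 2L, simplify = FALSE)
    pp <- vapply(pairs, function(pr) perf(setdiff(kept, pr)), numeric(1))
    drop_pair <- pairs[[which.min(pp)]]
    kept <- setdiff(kept, drop_pair)
    rejected <- c(rejected, drop_pair)
    pa <- vapply(rejected, function(f) perf(c(kept, f)), numeric(1))
    back <- rejected[which.min(pa)]
    kept <- c(kept, back)
    rejected <- setdiff(rejected, back)
    hist[[it]] <- data.frame(iteration = it,
                             removed1 = drop_pair[1], removed2 = drop_pair[2],
                             readded = back, performance = min(pa),
                             stringsAsFactors = FALSE)
  }
  list(survivor = kept,
       history = do.call(rbind, hist),
       eliminationOrder = rejected)
}

#' Run the full feature-importance battery
#'
#' Mutual information of each feature with the predicted labels, the
#' leave-one-out and single-feature performance distances, and the sequential
#' remove-two-add-one selection, with one shared seed so that performance
#' differences reflect features rather than restart luck.
#'
#' @param features feature table (training patterns).
#' @param z observed binary labels.
#' @param predicted predicted labels used for mutual information; computed
#'   from a full-feature fit when `NULL`.
#' @inheritParams subsetPerformance
#' @return list with `mutualInformation`, `leaveOneOut`, `singleFeature`,
#'   `sequential`.
#' @export
importanceBattery <- function(features, z, predicted = NULL, restarts = 10L,
                              seed = 1L, ...) {
  features <- featureInput(features)
  if (is.null(predicted)) {
    fit <- fitNoisyLogistic(features, z, restarts = restarts, seed = seed, ...)
    predicted <- as.integer(classifyPatterns(fit, features)$predicted)
  }
  list(mutualInformation = featureMutualInformation(features, predicted),
       leaveOneOut = leaveOneOutImportance(features, z, restarts, seed, ...),
       singleFeature = singleFeatureImportance(features, z, restarts, seed, ...),
       sequential = sequentialSelection(features, z, restarts, seed, ...))
}

#' Write an importance report to TSV + JSON
#' @param report list from [importanceBattery()].
#' @param prefix output path prefix (writes `<prefix>.tsv` and `<prefix>.json`).
#' @export
writeImportanceReport <- function(report, prefix) {
  fn <- names(report$leaveOneOut)
  d <- data.frame(feature = fn,
                  mutual_information = report$mutualInformation[fn],
                  leave_one_out = report$leaveOneOut[fn],
                  single_feature = report$singleFeature[fn],
                  row.names = NULL)
  utils::write.table(d, paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(survivor = report$sequential$survivor,
         eliminationOrder = report$sequential$eliminationOrder,
         history = report$sequential$history),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
}
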