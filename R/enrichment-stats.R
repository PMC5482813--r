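#' Group comparison of a feature between pattern classes
#'
#' Two-sided equal-variance t-test and Mann-Whitney U test of the feature
#' values in two groups, with Bonferroni adjustment for `nTests` comparisons
#' (p multiplied by `nTests`, capped at 1). With zero pooled variance the t
#' statistic is undefined and only the U test is reported.
#'
#' @param a,b numeric feature values of the two groups.
#' @param nTests number of tests in the family (e.g. 13 features).
#' @return data.frame with rows `t` and `mann-whitney`: `statistic`,
#'   `p_value`, `p_bonferroni`, and the group means.
#' @export
compareGroups <- function(a, b, nTests = 1L) {
  stopifnot(length(a) >= 2L, length(b) >= 2L, nTests >= 1L)
  pooled_var <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
    (length(a) + length(b) - 2L)
  if (pooled_var > 0) {
    tt <- stats::t.test(a, b, var.equal = TRUE)
    t_stat <- unname(tt$statistic); t_p <- tt$p.value
  } else {
    warning("zero pooled variance: t statistic undefined, reporting U only")
    t_stat <- NA_real_; t_p <- NA_real_
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b))
  out <- data.frame(
    test = c("t", "mann-whitney"),
    statistic = c(t_stat, unname(wt$statistic)),
    p_value = c(t_p, wt$p.value),
    mean_a = mean(a), mean_b = mean(b), stringsAsFactors = FALSE)
  out$p_bonferroni <- pmin(out$p_value * nTests, 1)
  out
}

#' @describeIn compareGroups compare every feature between two pattern
#'   groups, Bonferroni-adjusted over the number of features.
#' @param features feature table.
#' @param group1,group2 logical or index vectors selecting the two groups of
#'   rows.
#' @export
compareFeatureGroups <- function(features, group1, group2) {
  features <- as.data.frame(features)
  n <- ncol(features)
  do.call(rbind, lapply(names(features), function(f) {
    d <- compareGroups(features[group1, f], features[group2, f], nTests = n)
    cbind(feature = f, d)
  }))
}

#' Upper-tail hypergeometric enrichment test
#'
#' Probability of observing at least `k` predicted-functional patterns in a
#' group of size `K`, when `n` of the `N` patterns are predicted functional
#' overall: `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`.
#'
#' @param k predicted-functional patterns inside the group.
#' @param K group size.
#' @param n predicted-functional patterns in total.
#' @param N total number of patterns.
#' @return the upper-tail p-value.
#' @export
hypergeomEnrich <- function(k, K, n, N) {
  if (k > min(K, n) || K > N || n > N || k < 0)
    stop("inconsistent counts: need k <= min(K, n) and K, n <= N")
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Uniform-repositioning permutation test for element position
#'
#' Null: a functional element is equally likely to sit at any position inside
#' any intron of its transcript where it wholly fits. Each simulation draws
#' the element start uniformly over all valid wholly-contained positions
#' across the introns (placements spanning an intron boundary are invalid),
#' and the returned fraction is the share of simulations in which the element
#' lands in the actual host intron or one closer to the CDS start. A small
#' fraction means the element sits closer to the CDS start than the null
#' predicts.
#'
#' @param intronLengths intron lengths (nt) in CDS order.
#' @param hostIndex index of the actual host intron.
#' @param elementLength element length (nt).
#' @param nSims number of simulations (default 1000).
#' @param seed optional integer seed.
#' @return fraction in \[0, 1\].
#' @export
repositioningTest <- function(intronLengths, hostIndex, elementLength,
                              nSims = 1000L, seed = NULL) {
  stopifnot(hostIndex >= 1L, hostIndex <= length(intronLengths))
  valid <- pmax(0, intronLengths - elementLength + 1)
  if (sum(valid) == 0)
    stop("element is longer than every intron: no valid placement")
  if (!is.null(seed)) set.seed(seed)
  host <- sample.int(length(intronLengths), nSims, replace = TRUE,
                     prob = valid / sum(valid))
  mean(host <= hostIndex)
}

#' @describeIn repositioningTest run the test for many transcripts and
#'   summarise by the share of transcripts whose fraction is at least 0.95.
#' @param transcripts list; each element a list with `intronLengths`,
#'   `hostIndex`, `elementLength` (and optionally `id`).
#' @export
repositioningSummary <- function(transcripts, nSims = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  res <- do.call(rbind, lapply(seq_along(transcripts), function(i) {
    tr <- transcripts[[i]]
    data.frame(id = if (!is.null(tr$id)) tr$id else as.character(i),
               fraction = repositioningTest(tr$intronLengths, tr$hostIndex,
                                            tr$elementLength, nSims),
               n_sims = nSims, stringsAsFactors = FALSE)
  }))
  list(results = res, share_ge_95 = mean(res$fraction >= 0.95))
}
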