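#' Fisher-discriminant embedding of the feature space
#'
#' Standardizes the features, projects them onto the top `nComponents`
#' principal components, and computes the Fisher discriminant direction
#' `w proportional to S_W^-1 (m1 - m0)` in PC space between functional and
#' non-functional patterns (partial patterns are projected but do not enter
#' `w`). The x-coordinate is the projection on `w`; the y-coordinate is the
#' projection on the leading principal direction of the data after removing
#' the `w` component, so the two axes are orthogonal in PC space. Axis signs
#' are oriented so the functional-class mean is positive on x.
#'
#' @param features raw feature table (patterns x features).
#' @param labels character vector per pattern (`functional`,
#'   `non-functional`, `partial`) or a [PatternSet-class].
#' @param nComponents number of principal components retained (default 7).
#' @param ridge relative ridge added to `S_W` when it is singular.
#' @return a [FisherEmbedding-class].
#' @export
fisherEmbedding <- function(features, labels, nComponents = 7L,
                            ridge = 1e-6) {
  if (is(labels, "PatternSet")) labels <- patternLabels(labels)
  m <- featureInput(features)
  labels <- as.character(labels[rownames(m)])
  if (ncol(m) < nComponents) nComponents <- ncol(m)
  std <- standardizeFeatures(m)
  pca <- stats::prcomp(std$x, center = TRUE, scale. = FALSE)
  rot <- pca$rotation[, seq_len(nComponents), drop = FALSE]
  Z <- pca$x[, seq_len(nComponents), drop = FALSE]
  f <- labels == "functional"; n <- labels == "non-functional"
  if (!any(f) || !any(n))
    stop("both the functional and the non-functional class must be non-empty")
  m1 <- colMeans(Z[f, , drop = FALSE]); m0 <- colMeans(Z[n, , drop = FALSE])
  SW <- crossprod(sweep(Z[f, , drop = FALSE], 2L, m1)) +
        crossprod(sweep(Z[n, , drop = FALSE], 2L, m0))
  w <- tryCatch(solve(SW, m1 - m0), error = function(e) {
    message("within-class scatter is singular; applying ridge regularization")
    solve(SW + diag(ridge * sum(diag(SW)) / ncol(SW), ncol(SW)), m1 - m0)
  })
  w <- w / sqrt(sum(w^2))
  xs <- drop(Z %*% w)
  if (mean(xs[f]) < mean(xs[n])) { w <- -w; xs <- -xs }
  resid <- Z - outer(drop(Z %*% w), w)
  pc2 <- stats::prcomp(resid, center = TRUE, scale. = FALSE)$rotation[, 1L]
  if (pc2[which.max(abs(pc2))] < 0) pc2 <- -pc2  # deterministic sign
  ys <- drop(resid %*% pc2)
  new("FisherEmbedding",
      coordinates = data.frame(pattern = rownames(m), x = xs, y = ys,
                               label = labels, stringsAsFactors = FALSE),
      direction = w, rotation = rot, center = std$center, scale = std$scale)
}

setMethod("show", "FisherEmbedding", function(object) {
  cat("FisherEmbedding of", nrow(object@coordinates), "patterns on",
      length(object@direction), "principal components\n")
})

#' @describeIn fisherEmbedding scatter plot of the embedding (x = Fisher
#'   discriminant axis, y = orthogonal principal direction), colored by label.
#' @param x a [FisherEmbedding-class].
#' @param y ignored.
#' @param ... passed to [graphics::plot()].
#' @export
setMethod("plot", signature(x = "FisherEmbedding", y = "missing"),
  function(x, y, ...) {
    co <- x@coordinates
    cols <- c(functional = "goldenrod2", `non-functional` = "steelblue4",
              partial = "turquoise3")
    graphics::plot(co$x, co$y, col = cols[co$label], pch = 19, cex = 0.6,
                   xlab = "Fisher discriminant", ylab = "orthogonal PC", ...)
    graphics::legend("topright", legend = names(cols), col = cols, pch = 19,
                     bty = "n", cex = 0.8)
    invisible(x)
  })

#' Write an embedding to TSV
#' @param embedding a [FisherEmbedding-class].
#' @param file output path.
#' @export
writeEmbedding <- function(embedding, file) {
  utils::write.table(embedding@coordinates, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
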