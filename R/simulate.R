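#' Build a simulator configuration
#'
#' Defaults emulate the statistical structure of the real architecture data:
#' a minority functional class (about a tenth of columns) whose introns have
#' an older origin (root-presence bias 0.95 vs 0.6), a lower loss rate
#' (1.5e-4 vs 6e-4 events/MY against a shared gain rate of 2e-4), and
#' 5'-biased positions along the CDS (Beta(1,6) relative position vs uniform
#' for the background); one-sided label noise with completeness 0.2. See the
#' methods vignette for the rationale behind each value.
#'
#' @param tree a [DatedTree-class] (default: the 28-species fixture).
#' @param nSets number of ortholog sets.
#' @param meanColumns mean intron-bearing columns per set.
#' @param pFunctional functional-class probability per column.
#' @param gainFunctional,lossFunctional,gainBackground,lossBackground CTMC
#'   rates in events/MY.
#' @param rootP1Functional,rootP1Background root presence probabilities.
#' @param missingShape1,missingShape2 Beta parameters of the per-set missing
#'   species fraction.
#' @param missingZero probability that a set has complete species coverage.
#' @param cdsMeanLog,cdsSdLog lognormal parameters of CDS length (nt).
#' @param posShape1Functional,posShape2Functional,posShape1Background,posShape2Background
#'   Beta parameters of relative junction position per class.
#' @param intronMeanLog,intronSdLog lognormal parameters of intron length.
#' @param elementLength functional element length (nt).
#' @param theta11 label completeness.
#' @param seed integer seed.
#' @return a [SimConfig-class].
#' @export
simConfig <- function(tree = exampleTree(), nSets = 200L, meanColumns = 6,
                      pFunctional = 0.1,
                      gainFunctional = 2e-4, lossFunctional = 1.5e-4,
                      gainBackground = 2e-4, lossBackground = 6e-4,
                      rootP1Functional = 0.95, rootP1Background = 0.6,
                      missingShape1 = 2, missingShape2 = 5,
                      missingZero = 0.4,
                      cdsMeanLog = log(2800), cdsSdLog = 0.35,
                      posShape1Functional = 1, posShape2Functional = 6,
                      posShape1Background = 1, posShape2Background = 1,
                      intronMeanLog = log(1500), intronSdLog = 0.6,
                      elementLength = 20L, theta11 = 0.2, seed = 1L) {
  new("SimConfig", tree = tree, nSets = as.integer(nSets),
      meanColumns = meanColumns, pFunctional = pFunctional,
      gainFunctional = gainFunctional, lossFunctional = lossFunctional,
      gainBackground = gainBackground, lossBackground = lossBackground,
      rootP1Functional = rootP1Functional, rootP1Background = rootP1Background,
      missingShape1 = missingShape1, missingShape2 = missingShape2,
      missingZero = missingZero,
      cdsMeanLog = cdsMeanLog, cdsSdLog = cdsSdLog,
      posShape1Functional = posShape1Functional,
      posShape2Functional = posShape2Functional,
      posShape1Background = posShape1Background,
      posShape2Background = posShape2Background,
      intronMeanLog = intronMeanLog, intronSdLog = intronSdLog,
      elementLength = as.integer(elementLength), theta11 = theta11,
      seed = as.integer(seed))
}

#' Simulate presence/absence evolution down the tree
#'
#' Draws `n` independent binary characters under the two-state CTMC: a root
#' state from `rootP1`, then transitions along each branch with the standard
#' two-state transition probabilities.
#'
#' @param tree a [DatedTree-class].
#' @param n number of characters (patterns).
#' @param gain,loss rates in events/MY.
#' @param rootP1 root presence probability; stationary value when `NULL`.
#' @param seed optional integer seed.
#' @return integer 0/1 matrix, `n` x leaves.
#' @export
simulateGainLoss <- function(tree, n, gain, loss, rootP1 = NULL, seed = NULL) {
  stopifnot(is(tree, "DatedTree"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(rootP1))
    rootP1 <- if (gain + loss > 0) gain / (gain + loss) else 0.5
  tr <- stats::reorder(tree@tree, "postorder")
  ntip <- length(tr$tip.label)
  nn <- ntip + tr$Nnode
  st <- matrix(NA_integer_, n, nn)
  st[, ntip + 1L] <- stats::rbinom(n, 1L, rootP1)
  for (e in rev(seq_len(nrow(tr$edge)))) {  # preorder
    par <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    P <- ctmcTransition(gain, loss, tr$edge.length[e])
    pr <- ifelse(st[, par] == 1L, P[4], P[2])
    st[, ch] <- stats::rbinom(n, 1L, pr)
  }
  out <- st[, seq_len(ntip), drop = FALSE]
  colnames(out) <- tr$tip.label
  out
}

#' One-sided label noise
#'
#' Observed labels `z` arise from true labels `y` with `z = 1` with
#' probability `theta11` when `y = 1`, and `z = 0` always when `y = 0`
#' (a non-functional pattern is never observed as functional).
#'
#' @param y true binary labels.
#' @param theta11 completeness probability in \[0, 1\].
#' @param seed optional integer seed.
#' @return integer vector of observed labels.
#' @export
applyLabelNoise <- function(y, theta11, seed = NULL) {
  stopifnot(theta11 >= 0, theta11 <= 1)
  if (!is.null(seed)) set.seed(seed)
  ifelse(y == 1L, stats::rbinom(length(y), 1L, theta11), 0L)
}

#' Simulate aligned gene architectures with embedded functional elements
#'
#' Generates ortholog sets of ternary architecture rows over the configured
#' tree: each intron-bearing column evolves under its class's gain/loss
#' process (conditioned on presence in human, mirroring the human-centred
#' ascertainment of the real data), junction positions are drawn from the
#' class's CDS-position distribution, per-set species subsets go missing, and
#' functional elements are written (into the BED output) for every occurrence
#' of a pattern whose observed label is functional after one-sided noise at
#' the unique-pattern level.
#'
#' @param config a [SimConfig-class].
#' @return list with `architectures`, `elements`, `intronLengths` (disk-format
#'   data.frames), `truth` (per unique pattern: `pattern`, `y`, `z`) and
#'   `columnClasses` (per occurrence column).
#' @export
simulateArchitectures <- function(config) {
  stopifnot(is(config, "SimConfig"))
  set.seed(config@seed)
  tree <- config@tree
  species <- leafNames(tree)
  human <- "Homo_sapiens"
  if (!(human %in% species))
    stop("the simulator tree must contain Homo_sapiens")
  nset <- config@nSets
  m_per_set <- 1L + stats::rpois(nset, max(config@meanColumns - 1, 0))
  total <- sum(m_per_set)
  set_of <- rep(seq_len(nset), m_per_set)
  cls <- stats::rbinom(total, 1L, config@pFunctional)  # 1 = functional class
  sim_class <- function(k, gain, loss, rootP1) {
    if (k == 0L) return(matrix(integer(), 0L, length(species),
                               dimnames = list(NULL, species)))
    v <- simulateGainLoss(tree, k, gain, loss, rootP1)
    for (round in seq_len(60L)) {   # condition on presence in human
      bad <- which(v[, human] == 0L)
      if (!length(bad)) break
      v[bad, ] <- simulateGainLoss(tree, length(bad), gain, loss, rootP1)
    }
    bad <- which(v[, human] == 0L)
    if (length(bad)) {
      warning("regeneration cap reached; forcing human presence in ",
              length(bad), " columns")
      v[bad, human] <- 1L
    }
    v[, species, drop = FALSE]
  }
  vals <- matrix(NA_integer_, total, length(species),
                 dimnames = list(NULL, species))
  vals[cls == 1L, ] <- sim_class(sum(cls == 1L), config@gainFunctional,
                                 config@lossFunctional, config@rootP1Functional)
  vals[cls == 0L, ] <- sim_class(sum(cls == 0L), config@gainBackground,
                                 config@lossBackground, config@rootP1Background)
  arch <- list(); intron_rows <- list()
  positions <- integer(total); cds_lens <- integer(total)
  intron_len <- integer(total)
  for (s in seq_len(nset)) {
    idx <- which(set_of == s)
    m <- length(idx)
    sid <- sprintf("set%04d", s)
    p_miss <- if (stats::runif(1) < config@missingZero) 0 else
      stats::rbeta(1, config@missingShape1, config@missingShape2)
    missing <- species != human & stats::runif(length(species)) < p_miss
    L <- max(round(stats::rlnorm(1, config@cdsMeanLog, config@cdsSdLog)),
             20L * (m + 1L))
    rel <- ifelse(cls[idx] == 1L,
                  stats::rbeta(m, config@posShape1Functional, config@posShape2Functional),
                  stats::rbeta(m, config@posShape1Background, config@posShape2Background))
    pos <- pmin(pmax(round(rel * L), 1L), L - 1L)
    while (anyDuplicated(pos)) {
      dup <- duplicated(pos)
      pos[dup] <- pmin(pmax(pos[dup] + sample(c(-3L, -2L, -1L, 1L, 2L, 3L),
                                              sum(dup), replace = TRUE), 1L), L - 1L)
    }
    ord <- order(pos)
    idx <- idx[ord]; pos <- pos[ord]
    positions[idx] <- pos; cds_lens[idx] <- L
    il <- pmax(round(stats::rlnorm(m, config@intronMeanLog, config@intronSdLog)),
               config@elementLength + 2L)
    intron_len[idx] <- il
    intron_rows[[s]] <- data.frame(set_id = sid, intron_index = seq_len(m),
                                   length = il, stringsAsFactors = FALSE)
    rows <- lapply(seq_along(species), function(j) {
      if (missing[j]) return(strrep("2", L))
      ch <- rep.int("0", L)
      ch[pos[vals[idx, j] == 1L]] <- "1"
      paste(ch, collapse = "")
    })
    arch[[s]] <- data.frame(set_id = sid, species = species,
                            architecture = unlist(rows),
                            stringsAsFactors = FALSE)
    # missing species are fully absent in the ternary encoding either way;
    # record the mask by overwriting simulated values for bookkeeping
    vals[idx, missing] <- 2L
  }
  arch <- do.call(rbind, c(arch, make.row.names = FALSE))
  introns <- do.call(rbind, c(intron_rows, make.row.names = FALSE))
  # collapse (untagged) to decide pattern-level truth and noisy labels
  cols <- encodeTernary(arch, human = human, species = species)
  ps <- collapsePatterns(cols, human = human)
  occ <- occurrences(ps)
  # map each surviving occurrence back to its generating column; the
  # alignment column index equals the junction position in this simulator
  col_key <- paste(sprintf("set%04d", set_of), positions)
  occ_cls <- cls[match(paste(occ$set_id, occ$column), col_key)]
  ids <- rownames(patternMatrix(ps))
  y <- as.integer(tapply(occ_cls, factor(occ$pattern, levels = ids),
                         function(v) any(v == 1L)))
  z <- applyLabelNoise(y, config@theta11)
  # elements for every occurrence of an observed-functional pattern
  el <- NULL
  tagged <- occ[occ$pattern %in% ids[z == 1L], ]
  if (nrow(tagged)) {
    gcol <- match(paste(tagged$set_id, tagged$column), col_key)
    il <- intron_len[gcol]
    # cumulative length of the introns preceding each column's intron,
    # in CDS-position order within each set
    o <- order(set_of, positions)
    cum <- stats::ave(intron_len[o], set_of[o], FUN = cumsum)
    prev_all <- numeric(total)
    prev_all[o] <- cum - intron_len[o]
    istart <- tagged$position + prev_all[gcol]
    off <- vapply(il - config@elementLength, function(v)
      sample.int(v + 1L, 1L) - 1L, integer(1))
    el <- data.frame(set_id = tagged$set_id,
                     start = istart + off,
                     end = istart + off + config@elementLength,
                     type = "TFBS", stringsAsFactors = FALSE)
  } else {
    el <- data.frame(set_id = character(), start = integer(),
                     end = integer(), type = character())
  }
  list(architectures = arch, elements = el, intronLengths = introns,
       truth = data.frame(pattern = ids, y = y, z = z,
                          stringsAsFactors = FALSE),
       columnClasses = data.frame(set_id = sprintf("set%04d", set_of),
                                  position = positions,
                                  functional_class = cls,
                                  stringsAsFactors = FALSE))
}

#' Simulate a labeled pattern set end to end
#'
#' Runs [simulateArchitectures()], encodes and tags the architectures, and
#' collapses them into a labeled [PatternSet-class] with pattern-level ground
#' truth.
#'
#' @param config a [SimConfig-class].
#' @return list with `patterns` (a [PatternSet-class]) and `truth`
#'   (data.frame `pattern`, `y`, `z`).
#' @export
simulatePatterns <- function(config) {
  sim <- simulateArchitectures(config)
  cols <- encodeTernary(sim$architectures, human = "Homo_sapiens")
  cols <- attachElements(cols, sim$elements, sim$intronLengths)
  ps <- collapsePatterns(cols)
  list(patterns = ps, truth = sim$truth)
}

#' Simulate feature vectors with noisy labels from a known logistic model
#'
#' Features are iid standard normal; true labels follow the logistic model
#' `p(y=1|x) = 1/(1 + exp(-(omega' x) + omega0))`; observed labels apply
#' one-sided noise with completeness `theta11`.
#'
#' @param n number of patterns.
#' @param omega true feature weights.
#' @param omega0 true offset (plus-sign convention).
#' @param theta11 label completeness.
#' @param seed optional integer seed.
#' @return list with `x` (matrix), `y`, `z`.
#' @export
simulateFeatures <- function(n, omega, omega0 = 0, theta11 = 0.2,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- length(omega)
  x <- matrix(stats::rnorm(n * d), n, d,
              dimnames = list(NULL, paste0("F", seq_len(d))))
  p <- probFunctional(x, omega, omega0)
  y <- stats::rbinom(n, 1L, p)
  z <- applyLabelNoise(y, theta11)
  list(x = x, y = y, z = z)
}
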