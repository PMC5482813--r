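#' @import methods
NULL

setOldClass("phylo")

#' DatedTree: a rooted, dated (ultrametric) phylogeny
#'
#' Wraps an [ape::phylo] tree whose branch lengths are in million years (MY)
#' and caches the age of every node (leaves at 0 MY, root oldest). Leaf ages
#' are allowed to deviate from zero by at most `tolerance` times the root age,
#' absorbing the rounding present in published divergence-time trees.
#'
#' @slot tree an `ape::phylo` object (rooted, with branch lengths in MY).
#' @slot ages numeric vector of node ages in MY, indexed by ape node number
#'   (tips `1..Ntip`, internals `Ntip+1..Ntip+Nnode`).
#' @slot tolerance relative ultrametricity tolerance used at validation.
#'
#' @seealso [datedTree()], [mrcaAge()], [nodeAges()]
#' @exportClass DatedTree
setClass("DatedTree",
  slots = c(tree = "phylo", ages = "numeric", tolerance = "numeric"))

setValidity("DatedTree", function(object) {
  tr <- object@tree
  ntip <- length(tr$tip.label)
  if (is.null(tr$edge.length))
    return("tree has no branch lengths")
  if (anyDuplicated(tr$tip.label))
    return("leaf names are not unique")
  if (length(object@ages) != ntip + tr$Nnode)
    return("ages vector length does not match node count")
  root_age <- max(object@ages)
  tol <- object@tolerance * root_age
  tip_ages <- object@ages[seq_len(ntip)]
  worst <- which.max(abs(tip_ages))
  if (abs(tip_ages[worst]) > tol)
    return(sprintf("tree is not ultrametric: leaf '%s' has age %.6g MY (> tolerance %.6g)",
                   tr$tip.label[worst], tip_ages[worst], tol))
  parent <- tr$edge[, 1L]; child <- tr$edge[, 2L]
  bad <- which(object@ages[parent] <= object@ages[child] - tol)
  bad <- bad[child[bad] > ntip]
  if (length(bad))
    return("an internal node is not older than its children")
  TRUE
})

#' PatternSet: unique intron presence-absence patterns
#'
#' A collection of unique ternary patterns (one row per unique pattern, one
#' column per species, values in \{0, 1, 2\}: 1 = last nucleotide of an exon,
#' i.e. an intron immediately downstream; 0 = intron absent; 2 = gap/missing
#' ortholog), together with each pattern's multiplicity, occurrence records
#' and functionality label.
#'
#' @slot patterns integer matrix, unique patterns x species, values 0/1/2;
#'   rownames are pattern ids, colnames species names.
#' @slot multiplicity integer vector, occurrences per unique pattern.
#' @slot label character vector in `"functional"`, `"non-functional"`,
#'   `"partial"`: functional iff every occurrence carries at least one
#'   functional-element tag, non-functional iff none does, partial otherwise.
#' @slot occurrences data.frame with one row per surviving alignment column:
#'   `pattern`, `set_id`, `column`, `position` (1-based nt from CDS start to
#'   the exon-exon junction on the human transcript), `cds_length`, `tags`
#'   (comma-joined element types, `""` if none).
#' @slot human name of the reference (human) species column.
#'
#' @seealso [collapsePatterns()], [buildFeatureTable()]
#' @exportClass PatternSet
setClass("PatternSet",
  slots = c(patterns = "matrix", multiplicity = "integer",
            label = "character", occurrences = "data.frame",
            human = "character"))

setValidity("PatternSet", function(object) {
  p <- object@patterns
  if (!all(p %in% 0:2)) return("pattern values must be in {0,1,2}")
  if (is.null(rownames(p)) || is.null(colnames(p)))
    return("pattern matrix must have pattern ids as rownames and species as colnames")
  n <- nrow(p)
  if (length(object@multiplicity) != n || length(object@label) != n)
    return("multiplicity/label length must equal the number of unique patterns")
  if (any(object@multiplicity < 1L)) return("multiplicity must be >= 1")
  if (!all(object@label %in% c("functional", "non-functional", "partial")))
    return("labels must be 'functional', 'non-functional' or 'partial'")
  if (!(object@human %in% colnames(p)))
    return(sprintf("human species '%s' is not a pattern column", object@human))
  if (n > 0 && !all(p[, object@human] == 1L))
    return("every unique pattern must have value 1 in the human species")
  occ <- object@occurrences
  need <- c("pattern", "set_id", "column", "position", "cds_length", "tags")
  if (!all(need %in% names(occ)))
    return("occurrences must have columns pattern, set_id, column, position, cds_length, tags")
  cnt <- table(factor(occ$pattern, levels = rownames(p)))
  if (n > 0 && !all(as.integer(cnt) == object@multiplicity))
    return("multiplicity must equal the number of occurrence records per pattern")
  TRUE
})

#' GainLossModel: homogeneous two-state intron gain/loss model
#'
#' A two-state continuous-time Markov chain on the dated tree: state 1 =
#' intron present, state 0 = absent, gain rate (0 to 1) and loss rate (1 to 0)
#' in events per MY, constant across branches, with root state distribution
#' `(1 - pi1, pi1)`. Used to score how typical a pattern's evolutionary
#' history is via its log-likelihood.
#'
#' @slot gain gain rate (events/MY, >= 0).
#' @slot loss loss rate (events/MY, >= 0).
#' @slot pi1 root probability of state 1 (present).
#' @slot logLik total (weighted) data log-likelihood achieved at the fit;
#'   `NA` for hand-constructed models.
#' @slot converged logical, optimizer convergence flag.
#'
#' @seealso [fitGainLoss()], [patternLogLik()]
#' @exportClass GainLossModel
setClass("GainLossModel",
  slots = c(gain = "numeric", loss = "numeric", pi1 = "numeric",
            logLik = "numeric", converged = "logical"))

setValidity("GainLossModel", function(object) {
  if (length(object@gain) != 1L || !is.finite(object@gain) || object@gain < 0)
    return("gain rate must be a single finite number >= 0")
  if (length(object@loss) != 1L || !is.finite(object@loss) || object@loss < 0)
    return("loss rate must be a single finite number >= 0")
  if (length(object@pi1) != 1L || object@pi1 < 0 || object@pi1 > 1)
    return("pi1 must be a probability")
  TRUE
})

#' NoisyLabelFit: fitted noisy-label logistic classifier
#'
#' Parameters and diagnostics of the logistic model with one-sided label
#' noise, trained by EM. The functional probability of a feature vector x is
#' `p(y=1|x) = 1 / (1 + exp(-(omega' x) + omega0))` (note that the offset
#' `omega0` enters the exponent with a plus sign), and an observed functional
#' label arises with probability `theta11` from a truly functional pattern and
#' never from a non-functional one (`theta01 = 0`).
#'
#' @slot omega named numeric vector of feature weights (on the standardized
#'   feature scale).
#' @slot omega0 scalar offset, sign convention as above.
#' @slot theta11 label-completeness parameter in \[0, 1\].
#' @slot threshold classification threshold T.
#' @slot center,scale standardization parameters applied to the features
#'   before scoring (scale 1 / center 0 for binary features).
#' @slot features feature names in training order.
#' @slot logLik observed-data log-likelihood at convergence (best restart).
#' @slot trajectory observed log-likelihood per EM iteration (best restart).
#' @slot responsibilities E-step posterior `p(y=1 | z, x)` per training row
#'   at convergence.
#' @slot restartSummary data.frame with per-parameter mean, sd and coefficient
#'   of variation across random restarts.
#' @slot converged logical; `iterations` EM iterations used (best restart).
#' @slot iterations integer.
#'
#' @seealso [fitNoisyLogistic()], [classifyPatterns()], [estimateP10()]
#' @exportClass NoisyLabelFit
setClass("NoisyLabelFit",
  slots = c(omega = "numeric", omega0 = "numeric", theta11 = "numeric",
            threshold = "numeric", center = "numeric", scale = "numeric",
            features = "character", logLik = "numeric",
            trajectory = "numeric", responsibilities = "numeric",
            restartSummary = "data.frame", converged = "logical",
            iterations = "integer"))

setValidity("NoisyLabelFit", function(object) {
  if (object@theta11 < 0 || object@theta11 > 1)
    return("theta11 must lie in [0, 1]")
  if (length(object@omega) && any(!is.finite(object@omega)))
    return("omega must be finite")
  if (object@threshold <= 0 || object@threshold >= 1)
    return("threshold must lie in (0, 1)")
  TRUE
})

#' FisherEmbedding: 2-D Fisher-discriminant view of the feature space
#'
#' Coordinates of every pattern on (x) the Fisher discriminant axis computed
#' between functional and non-functional patterns in the top principal
#' components of the standardized features, and (y) the first principal
#' direction of the data after removing the discriminant component.
#'
#' @slot coordinates data.frame: `pattern`, `x`, `y`, `label`.
#' @slot direction the discriminant direction in PC space (unit norm).
#' @slot rotation PCA rotation matrix used (features x components).
#' @slot center,scale standardization applied before PCA.
#'
#' @seealso [fisherEmbedding()]
#' @exportClass FisherEmbedding
setClass("FisherEmbedding",
  slots = c(coordinates = "data.frame", direction = "numeric",
            rotation = "matrix", center = "numeric", scale = "numeric"))

#' SimConfig: generative settings for the architecture simulator
#'
#' Parameters of the synthetic data generator that emulates the statistical
#' structure of the real architecture datasets: tree-structured intron
#' presence/absence with class-dependent loss rates and root-origin bias,
#' 5'-biased positions for functional introns, and one-sided label noise.
#' Defaults mirror the study conditions; see the methods vignette for the
#' rationale behind each value.
#'
#' @slot tree a [DatedTree-class].
#' @slot nSets number of simulated ortholog sets.
#' @slot meanColumns mean number of intron-bearing alignment columns per set.
#' @slot pFunctional probability that a column belongs to the functional class.
#' @slot gainFunctional,lossFunctional CTMC rates (events/MY) for the
#'   functional class (lower loss than background).
#' @slot gainBackground,lossBackground CTMC rates for the background class.
#' @slot rootP1Functional,rootP1Background probability of presence at the
#'   root per class (functional introns have older origins).
#' @slot missingShape1,missingShape2 Beta parameters for the per-set fraction
#'   of missing (all-2) species.
#' @slot missingZero probability that a set has complete species coverage
#'   (zero-inflation of the missing fraction); complete sets are what lets
#'   identical patterns recur across ortholog sets and collapse with
#'   multiplicity > 1.
#' @slot cdsMeanLog,cdsSdLog lognormal parameters of the human CDS length (nt).
#' @slot posShape1Functional,posShape2Functional Beta parameters of the
#'   relative CDS position of functional-class junctions (5'-biased).
#' @slot posShape1Background,posShape2Background same for the background class.
#' @slot intronMeanLog,intronSdLog lognormal parameters of intron lengths (nt).
#' @slot elementLength length (nt) of the embedded functional elements.
#' @slot theta11 one-sided label noise: probability that a truly functional
#'   pattern is observed as labeled functional.
#' @slot seed integer seed driving all randomness.
#'
#' @seealso [simConfig()], [simulateArchitectures()], [simulatePatterns()]
#' @exportClass SimConfig
setClass("SimConfig",
  slots = c(tree = "DatedTree", nSets = "integer", meanColumns = "numeric",
            pFunctional = "numeric",
            gainFunctional = "numeric", lossFunctional = "numeric",
            gainBackground = "numeric", lossBackground = "numeric",
            rootP1Functional = "numeric", rootP1Background = "numeric",
            missingShape1 = "numeric", missingShape2 = "numeric",
            missingZero = "numeric",
            cdsMeanLog = "numeric", cdsSdLog = "numeric",
            posShape1Functional = "numeric", posShape2Functional = "numeric",
            posShape1Background = "numeric", posShape2Background = "numeric",
            intronMeanLog = "numeric", intronSdLog = "numeric",
            elementLength = "integer", theta11 = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  pr <- c(object@pFunctional, object@rootP1Functional, object@rootP1Background,
          object@theta11)
  if (any(pr < 0 | pr > 1)) return("probabilities must lie in [0, 1]")
  rt <- c(object@gainFunctional, object@lossFunctional,
          object@gainBackground, object@lossBackground)
  if (any(rt < 0) || any(!is.finite(rt))) return("rates must be finite and >= 0")
  if (object@nSets < 1L) return("nSets must be >= 1")
  if (object@elementLength < 1L) return("elementLength must be >= 1")
  TRUE
})
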