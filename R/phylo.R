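#' Build a dated phylogeny from a tree or newick text
#'
#' Node ages (in million years) are computed by summing branch lengths from
#' the root; the deepest leaf defines age 0 at the present. The tree must be
#' ultrametric within `tolerance` (relative to the root age): real
#' divergence-time trees are nominally ultrametric but rounded, so a small
#' slack avoids spurious rejection.
#'
#' @param tree an [ape::phylo] object, a newick string, or a file path.
#' @param tolerance maximum allowed leaf age as a fraction of the root age.
#' @return a [DatedTree-class].
#' @examples
#' tr <- datedTree("((A:1,B:1):1,C:2);")
#' rootAge(tr)            # 2
#' mrcaAge(tr, c("A", "C"))  # 2
#' @export
datedTree <- function(tree, tolerance = 0.001) {
  if (is.character(tree)) {
    tree <- tryCatch({
      tr <- if (length(tree) == 1L && grepl("\\(", tree))
        ape::read.tree(text = tree) else ape::read.tree(tree)
      if (is.null(tr)) stop("empty result")
      tr
    }, error = function(e)
      stop("malformed newick: ", conditionMessage(e), call. = FALSE))
  }
  if (!inherits(tree, "phylo")) stop("'tree' must be a phylo object or newick text")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  depth <- ape::node.depth.edgelength(tree)
  root_age <- max(depth)
  ages <- root_age - depth
  ntip <- length(tree$tip.label)
  # snap near-zero leaf ages so downstream arithmetic is exact; validity
  # still sees the worst pre-snap deviation through `tolerance`
  tip_ages <- ages[seq_len(ntip)]
  worst <- which.max(abs(tip_ages))
  if (abs(tip_ages[worst]) > tolerance * root_age)
    stop(sprintf("tree is not ultrametric: leaf '%s' deviates from the present by %.6g MY",
                 tree$tip.label[worst], tip_ages[worst]))
  ages[seq_len(ntip)] <- 0
  new("DatedTree", tree = tree, ages = ages, tolerance = tolerance)
}

#' Read a dated tree from a newick file
#' @inheritParams datedTree
#' @param file path to a newick file with branch lengths in MY.
#' @return a [DatedTree-class].
#' @export
readDatedTree <- function(file, tolerance = 0.001) {
  datedTree(ape::read.tree(file), tolerance = tolerance)
}

#' Serialize a dated tree to newick
#' @param x a [DatedTree-class].
#' @param file optional path; if `NULL` the newick string is returned.
#' @export
writeDatedTree <- function(x, file = NULL) {
  stopifnot(is(x, "DatedTree"))
  if (is.null(file)) ape::write.tree(x@tree) else ape::write.tree(x@tree, file = file)
}

#' @rdname DatedTree-class
#' @export
setMethod("nodeAges", "DatedTree", function(x) {
  tr <- x@tree
  nm <- c(tr$tip.label, if (!is.null(tr$node.label)) tr$node.label
          else paste0("node", seq_len(tr$Nnode) + length(tr$tip.label)))
  stats::setNames(x@ages, nm)
})

#' @rdname DatedTree-class
#' @export
setMethod("rootAge", "DatedTree", function(x) max(x@ages))

#' @rdname DatedTree-class
#' @export
setMethod("leafNames", "DatedTree", function(x) x@tree$tip.label)

setMethod("show", "DatedTree", function(object) {
  cat("DatedTree with", length(object@tree$tip.label), "leaves; root age",
      format(rootAge(object)), "MY\n")
})

#' Age of the most recent common ancestor of a set of species
#'
#' @param x a [DatedTree-class].
#' @param species non-empty character vector of leaf names.
#' @return the MRCA node age in MY (0 for a single species: a leaf is its own
#'   ancestor).
#' @export
mrcaAge <- function(x, species) {
  stopifnot(is(x, "DatedTree"))
  species <- unique(as.character(species))
  if (length(species) == 0L) stop("'species' must be non-empty")
  idx <- match(species, x@tree$tip.label)
  if (anyNA(idx))
    stop("unknown species: ", paste(species[is.na(idx)], collapse = ", "))
  if (length(idx) == 1L) return(x@ages[idx])
  x@ages[ape::getMRCA(x@tree, idx)]
}

#' Read a clade map (group -> species) from a two-column TSV
#'
#' @param file TSV with columns `group` and `species`.
#' @param tree optional [DatedTree-class]; if given, every species must be a
#'   leaf of the tree.
#' @return named list of character vectors.
#' @export
readCladeMap <- function(file, tree = NULL) {
  d <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("group", "species") %in% names(d)))
    stop("clade map must have columns 'group' and 'species'")
  clades <- split(d$species, d$group)
  if (!is.null(tree)) {
    unknown <- setdiff(unlist(clades), leafNames(tree))
    if (length(unknown))
      stop("clade map species not in tree: ", paste(unknown, collapse = ", "))
  }
  clades
}

#' The packaged 28-species fixture tree
#'
#' A synthetic stand-in for a dated 28-species eukaryotic phylogeny (Ecdysozoa
#' topology, round approximate divergence times in MY). It is a test fixture
#' with plausible ages, not a reference chronogram.
#'
#' @return a [DatedTree-class] with 28 leaves.
#' @export
exampleTree <- function() {
  readDatedTree(system.file("extdata", "tree_28species_synthetic.nwk",
                            package = "funtron"))
}

#' The default clade map for the fixture species
#'
#' Groups (amphibian, fish, bird, fungi, plant, protist) matching the clade
#' presence features; *Anolis carolinensis* is grouped with the amphibians,
#' following the grouping that defines those features. Override with
#' [readCladeMap()] if a different grouping is wanted.
#'
#' @return named list of character vectors.
#' @export
exampleClades <- function() {
  readCladeMap(system.file("extdata", "clades_28species.tsv",
                           package = "funtron"))
}
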