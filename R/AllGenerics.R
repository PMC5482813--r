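#' @rdname DatedTree-class
#' @param x a `DatedTree`
#' @export
setGeneric("nodeAges", function(x) standardGeneric("nodeAges"))

#' @rdname DatedTree-class
#' @export
setGeneric("rootAge", function(x) standardGeneric("rootAge"))

#' @rdname DatedTree-class
#' @export
setGeneric("leafNames", function(x) standardGeneric("leafNames"))

#' @rdname PatternSet-class
#' @param x a `PatternSet`
#' @export
setGeneric("nPatterns", function(x) standardGeneric("nPatterns"))

#' @rdname PatternSet-class
#' @export
setGeneric("patternMatrix", function(x) standardGeneric("patternMatrix"))

#' @rdname PatternSet-class
#' @export
setGeneric("multiplicity", function(x) standardGeneric("multiplicity"))

#' @rdname PatternSet-class
#' @export
setGeneric("patternLabels", function(x) standardGeneric("patternLabels"))

#' @rdname PatternSet-class
#' @export
setGeneric("occurrences", function(x) standardGeneric("occurrences"))

#' @rdname PatternSet-class
#' @export
setGeneric("humanSpecies", function(x) standardGeneric("humanSpecies"))
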