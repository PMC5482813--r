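#' Read aligned gene architectures from TSV
#'
#' One row per (ortholog set, species): `set_id`, `species`, `architecture`,
#' the latter a string over \{0,1,2\} giving the species' row of the aligned
#' ternary gene-architecture representation (1 = last nucleotide of a
#' non-terminal exon, 2 = gap or missing data, 0 = any other nucleotide).
#' All rows of a set must have equal length; species absent from a set are
#' treated as entirely missing.
#'
#' @param file path to the TSV.
#' @return data.frame with columns `set_id`, `species`, `architecture`.
#' @export
readArchitectures <- function(file) {
  d <- utils::read.delim(file, colClasses = "character")
  need <- c("set_id", "species", "architecture")
  if (!all(need %in% names(d)))
    stop("architecture TSV must have columns set_id, species, architecture")
  d[need]
}

#' @rdname readArchitectures
#' @param arch architectures data.frame.
#' @export
writeArchitectures <- function(arch, file) {
  utils::write.table(arch, file, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Encode aligned architectures into ternary pattern columns
#'
#' Every alignment column that marks an exon end (value 1) in at least one
#' species becomes one ternary pattern occurrence. For the human (reference)
#' species the junction position is recorded as the 1-based count of human
#' non-gap CDS nucleotides from the CDS start through the junction nucleotide
#' inclusive, and the human CDS length as the total count of human non-gap
#' nucleotides.
#'
#' @param arch data.frame as returned by [readArchitectures()] (may span many
#'   ortholog sets).
#' @param human name of the reference species.
#' @param species optional character vector fixing the species universe and
#'   order; defaults to the species seen in `arch` (human first).
#' @return list with `values` (integer matrix, occurrence columns x species)
#'   and `info` (data.frame `set_id`, `column`, `position`, `cds_length`,
#'   `tags`).
#' @export
encodeTernary <- function(arch, human = "Homo_sapiens", species = NULL) {
  if (is.null(species)) species <- unique(arch$species)
  vals <- list(); info <- list()
  for (sid in unique(arch$set_id)) {
    a <- arch[arch$set_id == sid, ]
    len <- unique(nchar(a$architecture))
    if (length(len) != 1L)
      stop(sprintf("set '%s': species rows have unequal aligned lengths", sid))
    if (anyDuplicated(a$species))
      stop(sprintf("set '%s': duplicated species row", sid))
    m <- matrix(2L, nrow = length(species), ncol = len,
                dimnames = list(species, NULL))
    for (k in seq_len(nrow(a))) {
      if (!(a$species[k] %in% species)) next
      row <- as.integer(strsplit(a$architecture[k], "")[[1]])
      if (any(is.na(row) | row > 2L))
        stop(sprintf("set '%s', species '%s': architecture characters must be 0/1/2",
                     sid, a$species[k]))
      m[a$species[k], ] <- row
    }
    keep <- which(colSums(m == 1L) > 0L)
    if (!length(keep)) next
    hrow <- m[human, ]
    cds_len <- sum(hrow != 2L)
    cum_nt <- cumsum(hrow != 2L)
    vals[[sid]] <- t(m[, keep, drop = FALSE])
    info[[sid]] <- data.frame(
      set_id = sid, column = keep,
      position = ifelse(hrow[keep] == 1L, cum_nt[keep], NA_integer_),
      cds_length = if (cds_len > 0L) cds_len else NA_integer_,
      tags = "", stringsAsFactors = FALSE)
  }
  if (!length(vals))
    return(list(values = matrix(integer(), 0, length(species),
                                dimnames = list(NULL, species)),
                info = data.frame(set_id = character(), column = integer(),
                                  position = integer(), cds_length = integer(),
                                  tags = character())))
  list(values = do.call(rbind, vals), info = do.call(rbind, c(info, make.row.names = FALSE)))
}

#' Read/write functional-element annotations (BED)
#'
#' Elements are intervals on the human pre-mRNA (CDS exons and introns
#' concatenated), 0-based half-open on disk per BED convention, with the BED
#' name field carrying the element type (e.g. `miRNA`, `snoRNA`, `TFBS`) and
#' the chromosome field carrying the ortholog-set id.
#'
#' @param file path to a BED file.
#' @return data.frame with columns `set_id`, `start`, `end` (0-based
#'   half-open), `type`.
#' @export
readElements <- function(file) {
  gr <- rtracklayer::import(file, format = "BED")
  data.frame(set_id = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             type = if (!is.null(gr$name)) gr$name else "element",
             stringsAsFactors = FALSE)
}

#' @rdname readElements
#' @param elements data.frame as returned by [readElements()].
#' @export
writeElements <- function(elements, file) {
  gr <- GenomicRanges::GRanges(
    seqnames = elements$set_id,
    ranges = IRanges::IRanges(start = elements$start + 1L, end = elements$end),
    name = elements$type)
  rtracklayer::export(gr, file, format = "BED")
}

#' Read/write per-intron lengths
#' @param file TSV with columns `set_id`, `intron_index`, `length` (human
#'   introns in CDS order).
#' @export
readIntronLengths <- function(file) {
  d <- utils::read.delim(file)
  if (!all(c("set_id", "intron_index", "length") %in% names(d)))
    stop("intron length TSV must have columns set_id, intron_index, length")
  d
}

#' @rdname readIntronLengths
#' @param introns intron-length data.frame.
#' @export
writeIntronLengths <- function(introns, file) {
  utils::write.table(introns, file, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Attach functional-element tags to ternary columns
#'
#' Maps each element interval to the human intron that fully contains it and
#' tags the corresponding junction column. Intron k of a transcript is the
#' intron immediately downstream of the k-th human junction in CDS order; its
#' pre-mRNA span is derived from the junction CDS offsets and the intron
#' lengths.
#'
#' @param cols ternary columns from [encodeTernary()].
#' @param elements data.frame from [readElements()].
#' @param intronLengths data.frame from [readIntronLengths()].
#' @param human reference species name.
#' @return `cols` with `info$tags` filled (comma-joined element types).
#' @export
attachElements <- function(cols, elements, intronLengths, human = "Homo_sapiens") {
  info <- cols$info
  for (sid in unique(info$set_id)) {
    idx <- which(info$set_id == sid & cols$values[, human] == 1L)
    if (!length(idx)) next
    ord <- idx[order(info$position[idx])]
    il <- intronLengths[intronLengths$set_id == sid, ]
    il <- il[order(il$intron_index), ]
    el <- elements[elements$set_id == sid, ]
    if (!nrow(el) || !nrow(il)) next
    if (nrow(il) < length(ord))
      stop(sprintf("set '%s': %d junctions but only %d intron lengths",
                   sid, length(ord), nrow(il)))
    cum_prev <- cumsum(c(0, il$length))[seq_along(ord)]
    # 0-based half-open pre-mRNA span of intron k
    ist <- info$position[ord] + cum_prev
    ien <- ist + il$length[seq_along(ord)]
    for (e in seq_len(nrow(el))) {
      k <- which(el$start[e] >= ist & el$end[e] <= ien)
      if (length(k)) {
        k <- k[1L]
        old <- info$tags[ord[k]]
        tg <- unique(c(if (nzchar(old)) strsplit(old, ",")[[1]], el$type[e]))
        info$tags[ord[k]] <- paste(tg, collapse = ",")
      }
    }
  }
  cols$info <- info
  cols
}

#' Filter ternary columns and collapse them into unique labeled patterns
#'
#' Filters are applied in order: (i) columns whose fraction of missing values
#' (code 2, denominator = total species count) is at least `missingThreshold`
#' are dropped; (ii) columns without any 1 are dropped; (iii) columns whose
#' human value is not 1 are dropped. Surviving identical ternary vectors are
#' grouped into unique patterns with their multiplicity, and labeled
#' `functional` if every occurrence carries at least one element tag,
#' `non-functional` if none does, and `partial` otherwise.
#'
#' @param cols ternary columns from [encodeTernary()] (possibly tagged by
#'   [attachElements()]).
#' @param human reference species name.
#' @param missingThreshold missing-value fraction at or above which a column
#'   is discarded (default 0.45).
#' @return a [PatternSet-class].
#' @export
collapsePatterns <- function(cols, human = "Homo_sapiens",
                             missingThreshold = 0.45) {
  v <- cols$values; info <- cols$info
  if (!(human %in% colnames(v)))
    stop(sprintf("human species '%s' is not among the pattern species", human))
  ns <- ncol(v)
  keep <- rowMeans(v == 2L) < missingThreshold
  keep <- keep & rowSums(v == 1L) > 0L
  keep <- keep & v[, human] == 1L
  v <- v[keep, , drop = FALSE]; info <- info[keep, , drop = FALSE]
  key <- apply(v, 1L, paste, collapse = "")
  first <- !duplicated(key)
  ukey <- key[first]
  um <- v[first, , drop = FALSE]
  mult <- as.integer(table(key)[ukey])
  ord <- order(-mult, ukey)
  um <- um[ord, , drop = FALSE]; ukey <- ukey[ord]; mult <- mult[ord]
  ids <- sprintf("UP%04d", seq_along(ukey))
  rownames(um) <- ids
  info$pattern <- ids[match(key, ukey)]
  tagged <- nzchar(info$tags)
  n_tag <- tapply(tagged, factor(info$pattern, levels = ids), sum)
  label <- ifelse(n_tag == mult, "functional",
                  ifelse(n_tag == 0L, "non-functional", "partial"))
  occ <- info[, c("pattern", "set_id", "column", "position", "cds_length", "tags")]
  occ <- occ[order(match(occ$pattern, ids), occ$set_id, occ$column), ]
  rownames(occ) <- NULL
  new("PatternSet", patterns = um, multiplicity = mult,
      label = as.character(label), occurrences = occ, human = human)
}

#' Per-function-type pattern labels
#'
#' Same labeling rule as the global label, restricted to occurrences tagged
#' with one element type: `functional` if every occurrence of the pattern
#' carries the type, `non-functional` if none does, `partial` otherwise.
#'
#' @param x a [PatternSet-class].
#' @param type element type (e.g. `"TFBS"`).
#' @return character vector of labels, one per unique pattern.
#' @export
labelByType <- function(x, type) {
  stopifnot(is(x, "PatternSet"))
  occ <- x@occurrences
  has <- vapply(strsplit(occ$tags, ","), function(t) type %in% t, logical(1))
  ids <- rownames(x@patterns)
  n_has <- tapply(has, factor(occ$pattern, levels = ids), sum)
  as.character(ifelse(n_has == x@multiplicity, "functional",
                      ifelse(n_has == 0L, "non-functional", "partial")))
}

#' @rdname PatternSet-class
#' @export
setMethod("nPatterns", "PatternSet", function(x) nrow(x@patterns))

#' @rdname PatternSet-class
#' @export
setMethod("patternMatrix", "PatternSet", function(x) x@patterns)

#' @rdname PatternSet-class
#' @export
setMethod("multiplicity", "PatternSet",
          function(x) stats::setNames(x@multiplicity, rownames(x@patterns)))

#' @rdname PatternSet-class
#' @export
setMethod("patternLabels", "PatternSet",
          function(x) stats::setNames(x@label, rownames(x@patterns)))

#' @rdname PatternSet-class
#' @export
setMethod("occurrences", "PatternSet", function(x) x@occurrences)

#' @rdname PatternSet-class
#' @export
setMethod("humanSpecies", "PatternSet", function(x) x@human)

setMethod("show", "PatternSet", function(object) {
  cat("PatternSet:", nrow(object@patterns), "unique patterns over",
      ncol(object@patterns), "species (",
      sum(object@multiplicity), "occurrences )\n")
  print(table(object@label))
})

#' Write/read a pattern set as TSV
#'
#' The TSV carries the species order and human species in `#`-prefixed header
#' lines, then one row per unique pattern: the ternary pattern string, its
#' multiplicity, its label, and semicolon-joined occurrence records
#' (`set_id|column|position|cds_length|tags`).
#'
#' @param x a [PatternSet-class].
#' @param file output path.
#' @export
writePatternSet <- function(x, file) {
  stopifnot(is(x, "PatternSet"))
  occ <- x@occurrences
  occ_str <- vapply(rownames(x@patterns), function(id) {
    o <- occ[occ$pattern == id, ]
    paste(sprintf("%s|%s|%s|%s|%s", o$set_id, o$column,
                  ifelse(is.na(o$position), "NA", o$position),
                  ifelse(is.na(o$cds_length), "NA", o$cds_length),
                  o$tags), collapse = ";")
  }, character(1))
  con <- file(file, "w"); on.exit(close(con))
  writeLines(c(paste0("# species=", paste(colnames(x@patterns), collapse = ";")),
               paste0("# human=", x@human)), con)
  utils::write.table(
    data.frame(pattern = apply(x@patterns, 1, paste, collapse = ""),
               multiplicity = x@multiplicity, label = x@label,
               occurrences = occ_str, stringsAsFactors = FALSE),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname writePatternSet
#' @export
readPatternSet <- function(file) {
  lines <- readLines(file)
  hdr <- grep("^# ", lines, value = TRUE)
  sp <- strsplit(sub("^# species=", "", hdr[grepl("^# species=", hdr)]), ";")[[1]]
  human <- sub("^# human=", "", hdr[grepl("^# human=", hdr)])
  d <- utils::read.delim(text = lines[!grepl("^# ", lines)],
                         colClasses = c("character", "integer", "character", "character"))
  m <- t(vapply(strsplit(d$pattern, ""), as.integer, integer(length(sp))))
  colnames(m) <- sp
  ids <- sprintf("UP%04d", seq_len(nrow(m)))
  rownames(m) <- ids
  occ <- do.call(rbind, lapply(seq_len(nrow(d)), function(i) {
    recs <- strsplit(d$occurrences[i], ";")[[1]]
    f <- do.call(rbind, lapply(strsplit(recs, "|", fixed = TRUE),
                               function(v) c(v, rep("", 5L))[1:5]))
    data.frame(pattern = ids[i], set_id = f[, 1], column = as.integer(f[, 2]),
               position = suppressWarnings(as.integer(f[, 3])),
               cds_length = suppressWarnings(as.integer(f[, 4])),
               tags = f[, 5], stringsAsFactors = FALSE)
  }))
  new("PatternSet", patterns = m, multiplicity = d$multiplicity,
      label = d$label, occurrences = occ, human = human)
}
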