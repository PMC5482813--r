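test_that("encodeTernary marks exon ends, gaps and human positions", {
  # no junctions anywhere -> no columns
  arch0 <- data.frame(set_id = "s1",
                      species = c("Homo_sapiens", "Mus_musculus"),
                      architecture = c("000000", "000000"))
  expect_equal(nrow(encodeTernary(arch0)$values), 0L)

  # one human intron after nucleotide 30 of a 90-nt CDS; other species absent
  h <- paste(c(rep("0", 29), "1", rep("0", 60)), collapse = "")
  arch1 <- data.frame(set_id = "s1", species = "Homo_sapiens",
                      architecture = h)
  cols <- encodeTernary(arch1, species = c("Homo_sapiens", "Mus_musculus"))
  expect_equal(nrow(cols$values), 1L)
  expect_equal(unname(cols$values[1, ]), c(1L, 2L))
  expect_equal(cols$info$position, 30L)
  expect_equal(cols$info$cds_length, 90L)

  # hand-drawn 3-species toy with gaps: human has a gap block, so its CDS
  # positions skip the gapped columns
  arch <- data.frame(
    set_id = "s2",
    species = c("Homo_sapiens", "Mus_musculus", "Gallus_gallus"),
    architecture = c("0102200", "0100010", "0002010"))
  cols <- encodeTernary(arch)
  # junction columns: 2 (human+mouse), 6 (mouse+chicken)
  expect_equal(cols$info$column, c(2L, 6L))
  expect_equal(unname(cols$values[1, ]), c(1L, 1L, 0L))
  expect_equal(unname(cols$values[2, ]), c(0L, 1L, 1L))
  # human row 0102210: non-gap counts 1,2,3,.,.,4,5 -> position at col2 = 2
  expect_equal(cols$info$position, c(2L, NA_integer_))
  expect_equal(cols$info$cds_length, c(5L, 5L))

  expect_error(encodeTernary(data.frame(
    set_id = "s3", species = c("a", "b"),
    architecture = c("010", "0100"))), "unequal")
})

test_that("collapsePatterns applies the filters in order and labels patterns", {
  sp <- c("Homo_sapiens", "s2", "s3", "s4")
  vals <- rbind(
    c(1, 2, 2, 0),  # 2/4 = 0.5 missing -> dropped by the 45% filter
    c(1, 0, 0, 0),  # kept
    c(0, 0, 0, 0),  # no 1 -> dropped
    c(0, 1, 0, 0),  # human not 1 -> dropped
    c(2, 1, 1, 1),  # human missing -> dropped
    c(1, 0, 0, 0))  # duplicate of the second -> multiplicity 2
  colnames(vals) <- sp
  ps <- collapsePatterns(makeCols(vals))
  expect_equal(nPatterns(ps), 1L)
  expect_equal(unname(multiplicity(ps)), 2L)
  expect_equal(sum(multiplicity(ps)), 2L)  # = surviving columns
  expect_true(all(patternMatrix(ps)[, "Homo_sapiens"] == 1L))

  # threshold boundary: exactly 45% missing is dropped, just under survives
  sp20 <- c("Homo_sapiens", paste0("x", 1:19))
  v <- matrix(0L, 2, 20, dimnames = list(NULL, sp20))
  v[, 1] <- 1L
  v[1, 2:10] <- 2L   # 9/20 = 0.45 -> dropped
  v[2, 2:9] <- 2L    # 8/20 = 0.40 -> kept
  ps <- collapsePatterns(makeCols(v))
  expect_equal(nPatterns(ps), 1L)
  expect_equal(sum(patternMatrix(ps) == 2L), 8L)
})

test_that("labels follow the all/none/mixed occurrence rule", {
  sp <- c("Homo_sapiens", "b", "c")
  v <- rbind(c(1, 0, 1), c(1, 0, 1))
  colnames(v) <- sp
  both <- makeCols(v, tags = c("miRNA", "TFBS"))
  expect_equal(unname(patternLabels(collapsePatterns(both))), "functional")
  mixed <- makeCols(v, tags = c("miRNA", ""))
  expect_equal(unname(patternLabels(collapsePatterns(mixed))), "partial")
  none <- makeCols(v, tags = c("", ""))
  expect_equal(unname(patternLabels(collapsePatterns(none))), "non-functional")
  # per-type sublabels
  ps <- collapsePatterns(makeCols(v, tags = c("miRNA,TFBS", "TFBS")))
  expect_equal(unname(labelByType(ps, "TFBS")), "functional")
  expect_equal(unname(labelByType(ps, "miRNA")), "partial")
  expect_equal(unname(labelByType(ps, "snoRNA")), "non-functional")
})

test_that("multiplicities match a brute-force hash count", {
  set.seed(31)
  sp <- c("Homo_sapiens", paste0("x", 1:5))
  v <- matrix(sample(0:2, 50 * 6, replace = TRUE, prob = c(.4, .4, .2)),
              50, 6, dimnames = list(NULL, sp))
  v[, 1] <- 1L
  keep <- rowMeans(v == 2) < 0.45 & rowSums(v == 1) > 0
  expected <- table(apply(v[keep, ], 1, paste, collapse = ""))
  ps <- collapsePatterns(makeCols(v))
  got <- stats::setNames(as.integer(multiplicity(ps)),
                         apply(patternMatrix(ps), 1, paste, collapse = ""))
  expect_equal(sum(multiplicity(ps)), sum(keep))
  expect_mapequal(as.list(got), as.list(stats::setNames(as.integer(expected),
                                                        names(expected))))
})

test_that("species-order permutation yields the same unique patterns", {
  set.seed(8)
  sp <- c("Homo_sapiens", paste0("x", 1:4))
  v <- matrix(sample(0:2, 40 * 5, replace = TRUE), 40, 5,
              dimnames = list(NULL, sp))
  v[, 1] <- 1L
  ps1 <- collapsePatterns(makeCols(v))
  perm <- c(3, 1, 5, 2, 4)
  ps2 <- collapsePatterns(makeCols(v[, perm]))
  k1 <- unname(apply(patternMatrix(ps1), 1, paste, collapse = ""))
  k2 <- unname(apply(patternMatrix(ps2)[, sp], 1, paste, collapse = ""))
  expect_setequal(k1, k2)
  m2 <- stats::setNames(as.integer(multiplicity(ps2)), k2)
  expect_equal(as.integer(m2[k1]), as.integer(multiplicity(ps1)))
})

test_that("element intervals are attached to the intron that contains them", {
  # human: junctions at CDS positions 10 and 20 (CDS length 30)
  h <- paste(c(rep("0", 9), "1", rep("0", 9), "1", rep("0", 10)), collapse = "")
  arch <- data.frame(set_id = "g1",
                     species = c("Homo_sapiens", "Mus_musculus"),
                     architecture = c(h, h))
  cols <- encodeTernary(arch)
  introns <- data.frame(set_id = "g1", intron_index = 1:2,
                        length = c(100L, 50L))
  # pre-mRNA spans: intron 1 = [10,110), intron 2 = [120,170)
  elements <- data.frame(set_id = "g1", start = c(125L, 15L),
                         end = c(140L, 108L), type = c("TFBS", "miRNA"))
  tagged <- attachElements(cols, elements, introns)
  expect_equal(tagged$info$tags, c("miRNA", "TFBS"))
  # an element crossing the exon boundary is attached nowhere
  crossing <- data.frame(set_id = "g1", start = 105L, end = 125L, type = "TFBS")
  expect_equal(attachElements(cols, crossing, introns)$info$tags, c("", ""))
})

test_that("pattern sets survive a TSV round trip", {
  sim <- simulatePatterns(simConfig(nSets = 15, seed = 3))
  ps <- sim$patterns
  f <- tempfile(fileext = ".tsv")
  writePatternSet(ps, f)
  back <- readPatternSet(f)
  expect_equal(patternMatrix(back), patternMatrix(ps))
  expect_equal(multiplicity(back), multiplicity(ps))
  expect_equal(patternLabels(back), patternLabels(ps))
  expect_equal(occurrences(back)$tags, occurrences(ps)$tags)
  expect_equal(humanSpecies(back), humanSpecies(ps))
})
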