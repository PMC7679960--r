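scoresFromRatios <- function(ratios, wt = "V", cons = "L") {
  n <- length(ratios)
  consensus <- ifelse(!is.na(ratios) & ratios > 1, cons, wt)
  S4Vectors::DataFrame(residueNumber = seq_len(n),
                       wtResidue = rep(wt, n),
                       consensusResidue = consensus,
                       fWt = ifelse(is.finite(ratios), 1 / (1 + ratios), 0),
                       fCons = ifelse(is.finite(ratios),
                                      ratios / (1 + ratios), 1),
                       ratio = ratios)
}

test_that("selection is strict, mask-aware and ignores undefined scores", {
  sc <- scoresFromRatios(c(1.0, 2.0, 2.5, 3.0))
  sel <- selectMutations(sc, 2.22)
  expect_equal(sel$residueNumber, c(3L, 4L))
  expect_equal(sel$notation, c("V3L", "V4L"))

  # exact threshold is excluded; infinity exceeds any finite threshold
  expect_equal(selectMutations(sc, 2.5)$residueNumber, 4L)
  expect_equal(selectMutations(scoresFromRatios(c(2, Inf)), 100)$residueNumber,
               2L)
  # nothing exceeds an infinite threshold
  expect_equal(nrow(selectMutations(sc, Inf)), 0L)
  # undefined ratios are never selected
  expect_equal(nrow(selectMutations(scoresFromRatios(c(NA, NA)), 1)), 0L)
  # a mask restricts selection
  sel2 <- selectMutations(sc, 1.5, IRanges::IRanges(3, 3))
  expect_equal(sel2$residueNumber, 3L)
})

test_that("selection agrees with a brute-force filter on random score sets", {
  set.seed(31)
  for (rep in 1:10) {
    sc <- randomScoreTable(200L)
    maskRanges <- if (rep %% 2) randomMaskRanges(200L) else NULL
    mask <- if (is.null(maskRanges)) NULL else asIRangesMask(maskRanges)
    t <- sample(c(1.0, 1.5, 2.22, 3, 5), 1L)
    got <- selectMutations(sc, t, mask)
    want <- bruteForceSelect(as.data.frame(sc), t, maskRanges)
    expect_identical(got$residueNumber, want$residueNumber)
    expect_identical(got$newResidue, want$consensusResidue)
    if (!is.null(maskRanges) && nrow(got))
      expect_true(all(vapply(got$residueNumber, function(p)
        any(p >= maskRanges$start & p <= maskRanges$end), TRUE)))
  }
})

test_that("constructs apply exactly the requested substitutions", {
  ref <- "MVLAVGLTKE"
  d <- buildConstruct(ref, parseMutation(c("V2L", "K9R")), "demo", 2)
  expect_equal(constructSequence(d), "MLLAVGLTRE")
  expect_equal(mutationCount(d), 2L)
  expect_equal(designThreshold(d), 2)
  expect_equal(mutations(d)$notation, c("V2L", "K9R"))

  empty <- buildConstruct(ref, parseMutation(character(0)), "wt")
  expect_equal(constructSequence(empty), ref)
  expect_equal(mutationPercent(empty), 0)

  expect_error(buildConstruct(ref, parseMutation("A2L"), "x"),
               "mismatch at position 2.*expected A.*has V")
  expect_error(buildConstruct(ref, parseMutation(c("V2L", "V2I")), "x"),
               "duplicate")
})

test_that("a 501-residue reference with 101 substitutions reports 20.2%", {
  set.seed(5)
  ref <- paste(sample(ORACLE_AA, 501L, replace = TRUE), collapse = "")
  chars <- strsplit(ref, "")[[1L]]
  at <- sort(sample.int(501L, 101L))
  muts <- S4Vectors::DataFrame(
    wtResidue = chars[at], residueNumber = at,
    newResidue = unname(vapply(chars[at], function(a)
      setdiff(ORACLE_AA, a)[1L], "")))
  d <- buildConstruct(ref, muts, "xCTcons", 2.22)
  expect_equal(mutationCount(d), 101L)
  expect_equal(mutationPercent(d), 20.2)
})

test_that("diffing a construct against its reference recovers the mutations", {
  set.seed(13)
  for (rep in 1:10) {
    len <- sample(20:120, 1L)
    ref <- paste(sample(ORACLE_AA, len, replace = TRUE), collapse = "")
    chars <- strsplit(ref, "")[[1L]]
    k <- sample.int(min(10L, len), 1L)
    at <- sort(sample.int(len, k))
    muts <- S4Vectors::DataFrame(
      wtResidue = chars[at], residueNumber = at,
      newResidue = unname(vapply(chars[at], function(a)
        sample(setdiff(ORACLE_AA, a), 1L), "")))
    d <- buildConstruct(ref, muts, "c")
    back <- diffConstruct(d, ref)
    expect_identical(back$residueNumber, at)
    expect_identical(back$wtResidue, muts$wtResidue)
    expect_identical(back$newResidue, muts$newResidue)
    expect_identical(back$notation, mutations(d)$notation)
  }
})

test_that("mutation notation round-trips through its parser", {
  set.seed(3)
  wt <- sample(ORACLE_AA, 50L, replace = TRUE)
  new <- vapply(wt, function(a) sample(setdiff(ORACLE_AA, a), 1L), "")
  pos <- sample.int(2000L, 50L)
  notation <- formatMutation(wt, pos, new)
  parsed <- parseMutation(notation)
  expect_identical(parsed$wtResidue, wt)
  expect_identical(parsed$residueNumber, as.integer(pos))
  expect_identical(parsed$newResidue, unname(new))
  expect_identical(formatMutation(parsed$wtResidue, parsed$residueNumber,
                                  parsed$newResidue), notation)
  expect_error(parseMutation("V12"), "malformed")
  expect_error(parseMutation("12L"), "malformed")
})

test_that("masks merge overlaps, keep disjoint ranges, reject bad input", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# TM segments", "5\t10", "8\t12"), f)
  m <- readMask(f)
  expect_equal(length(m), 1L)
  expect_equal(IRanges::start(m), 5L)
  expect_equal(IRanges::end(m), 12L)

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("# nothing", empty)
  expect_error(readMask(empty), "no ranges")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("10\t5"), bad)
  expect_error(readMask(bad), "line 1.*invalid range")

  long <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("1\t10", "20\t600"), long)
  expect_error(readMask(long, refLength = 501L), "line 2.*exceeds")

  # 12 disjoint segments: total masked length = sum of (end - start + 1)
  starts <- seq(1L, by = 40L, length.out = 12L)
  ends <- starts + sample(10:20, 12L, replace = TRUE)
  tm <- withr::local_tempfile(fileext = ".tsv")
  writeLines(sprintf("%d\t%d", starts, ends), tm)
  m12 <- readMask(tm)
  expect_equal(length(m12), 12L)
  expect_equal(sum(IRanges::width(m12)), sum(ends - starts + 1L))
})

test_that("mutation sets shrink monotonically as the threshold rises", {
  set.seed(47)
  for (rep in 1:25) {
    sc <- randomScoreTable(150L)
    ts <- sort(runif(2, 1, 6))
    hi <- selectMutations(sc, ts[2L])
    lo <- selectMutations(sc, ts[1L])
    expect_true(all(hi$residueNumber %in% lo$residueNumber))
    expect_lte(nrow(hi), nrow(lo))
  }
})

test_that("threshold sweeps name constructs by graded mutation load", {
  msa <- panelFixture()
  mp <- mapReference(msa, "REF")
  sc <- scorePositions(computeProfiles(msa), mp, msa)
  ref <- referenceSequence(msa, mp)
  panel <- sweepThresholds(sc, c(2.22, 4), NULL, ref, namePrefix = "xCT")
  expect_equal(vapply(panel, designName, ""), c("xCT_14.2", "xCT_20.2"))
  expect_equal(vapply(panel, designThreshold, 0), c(4, 2.22))  # descending
  expect_equal(vapply(panel, mutationCount, 0L), c(71L, 101L))

  # alternative naming by threshold
  byT <- sweepThresholds(sc, c(4), NULL, ref, namePrefix = "xCT",
                         nameByThreshold = TRUE)
  expect_equal(designName(byT[[1L]]), "xCT_t4")

  expect_warning(sweepThresholds(sc, c(4, 4), NULL, ref, "p"), "duplicate")
  expect_error(sweepThresholds(sc, numeric(0), NULL, ref, "p"),
               "at least one")
})

test_that("a threshold just below the smallest ratio selects every non-consensus position", {
  set.seed(91)
  sc <- randomScoreTable(80L)
  finite <- sc$ratio[!is.na(sc$ratio) & sc$ratio > 1 & is.finite(sc$ratio)]
  t <- min(finite) * 0.999
  sel <- selectMutations(sc, t)
  mutable <- sum(!is.na(sc$ratio) & sc$ratio > 1 &
                   sc$consensusResidue != sc$wtResidue)
  expect_equal(nrow(sel), mutable)
})
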