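# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from disk except files the tests themselves write.

# A 501-residue reference with deterministic, exactly known column ratios:
#   - nStrong columns with f(cons)/f(WT) = 5 (counts L5 / V1 / A4 over 10 rows)
#   - nMedium columns with f(cons)/f(WT) = 3 (counts L6 / V2 / A2)
#   - all remaining columns fully conserved (ratio 1)
# The reference row "REF" is all V and is one of the 10 counted rows.
# Thresholds 4 and 2.22 then select exactly nStrong and nStrong + nMedium
# mutations.
panelFixture <- function(refLen = 501L, nStrong = 71L, nMedium = 30L) {
  stopifnot(nStrong + nMedium <= refLen)
  strongCols <- seq_len(nStrong)
  mediumCols <- nStrong + seq_len(nMedium)
  nRows <- 10L
  mat <- matrix("V", nrow = nRows, ncol = refLen)
  mat[2:6,  strongCols] <- "L"   # counts: L5 V1(ref) A4 -> ratio 5
  mat[7:10, strongCols] <- "A"
  mat[2:7,  mediumCols] <- "L"   # counts: L6 V2(ref+row8) A2 -> ratio 3
  mat[9:10, mediumCols] <- "A"
  seqs <- apply(mat, 1L, paste, collapse = "")
  names(seqs) <- c("REF", sprintf("hom%02d", seq_len(nRows - 1L)))
  MSA(seqs)
}

# Random score tables for selection/monotonicity properties: a DataFrame in
# the scorePositions() layout with controllable ratio spread.
randomScoreTable <- function(n = 200L) {
  wt <- sample(ORACLE_AA, n, replace = TRUE)
  cons <- wt
  mutated <- runif(n) < 0.7
  cons[mutated] <- vapply(wt[mutated], function(a)
    sample(setdiff(ORACLE_AA, a), 1L), "")
  ratio <- ifelse(mutated, 1 + rexp(n, rate = 0.7), 1)
  ratio[mutated & runif(n) < 0.03] <- Inf
  undef <- runif(n) < 0.03
  ratio[undef] <- NA_real_
  cons[undef] <- NA_character_
  fWt <- ifelse(is.finite(ratio), 1 / (1 + ratio), 0)
  S4Vectors::DataFrame(residueNumber = seq_len(n), wtResidue = wt,
                       consensusResidue = cons,
                       fWt = fWt, fCons = fWt * ifelse(is.finite(ratio),
                                                       ratio, 0),
                       ratio = ratio)
}

# Reference sequence matching a random score table (wt residues in order).
scoreTableReference <- function(scores) {
  paste(scores$wtResidue, collapse = "")
}

randomMaskRanges <- function(refLen, nRanges = 3L) {
  starts <- sort(sample.int(refLen, nRanges))
  ends <- pmin(starts + sample.int(max(refLen %/% nRanges, 2L), nRanges),
               refLen)
  data.frame(start = starts, end = ends)
}

asIRangesMask <- function(maskRanges) {
  IRanges::reduce(IRanges::IRanges(maskRanges$start, maskRanges$end))
}
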