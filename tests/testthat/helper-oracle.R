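# Independent brute-force implementations used as oracles.
# Deliberately written with plain nested loops over character vectors and no
# shared code with the package internals.

ORACLE_AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

# Score every non-gap reference position of a plain named character vector
# of aligned sequences. Returns a data.frame comparable to scorePositions().
bruteForceScores <- function(seqs, refid, pseudocount = 0,
                             includeReference = TRUE) {
  rows <- lapply(seqs, function(s) strsplit(toupper(s), "")[[1L]])
  ref <- rows[[refid]]
  counted <- if (includeReference) rows else rows[names(rows) != refid]
  out <- list()
  pos <- 0L
  for (j in seq_along(ref)) {
    if (ref[j] == "-") next
    pos <- pos + 1L
    cnt <- setNames(numeric(length(ORACLE_AA)), ORACLE_AA)
    for (r in counted)
      if (r[j] %in% ORACLE_AA) cnt[r[j]] <- cnt[r[j]] + 1
    neff <- sum(cnt)
    wt <- ref[j]
    if (neff == 0 || !(wt %in% ORACLE_AA)) {
      out[[pos]] <- data.frame(residueNumber = pos, wtResidue = wt,
                               consensusResidue = NA_character_,
                               fWt = NA_real_, fCons = NA_real_,
                               ratio = NA_real_)
      next
    }
    f <- (cnt + pseudocount) / (neff + 20 * pseudocount)
    tied <- ORACLE_AA[f >= max(f) - 1e-12]
    cons <- if (wt %in% tied) wt else tied[1L]
    fwt <- f[[wt]]
    fc <- f[[cons]]
    ratio <- if (cons == wt) 1 else if (fwt == 0) Inf else fc / fwt
    out[[pos]] <- data.frame(residueNumber = pos, wtResidue = wt,
                             consensusResidue = cons, fWt = fwt,
                             fCons = fc, ratio = ratio)
  }
  do.call(rbind, out)
}

# Brute-force mutation selection: loop + the three membership conditions.
bruteForceSelect <- function(scoresDf, threshold, maskRanges = NULL) {
  picked <- integer(0)
  for (i in seq_len(nrow(scoresDf))) {
    r <- scoresDf$ratio[i]
    if (is.na(r)) next
    if (!(r > threshold)) next
    if (is.na(scoresDf$consensusResidue[i]) ||
        scoresDf$consensusResidue[i] == scoresDf$wtResidue[i]) next
    if (!is.null(maskRanges)) {
      inside <- FALSE
      for (k in seq_len(nrow(maskRanges)))
        if (scoresDf$residueNumber[i] >= maskRanges$start[k] &&
            scoresDf$residueNumber[i] <= maskRanges$end[k]) inside <- TRUE
      if (!inside) next
    }
    picked <- c(picked, i)
  }
  scoresDf[picked, , drop = FALSE]
}

# Random aligned sequences over amino acids plus occasional gaps/ambiguity.
randomAlignment <- function(nSeq, nCol, gapProb = 0.1, ambigProb = 0.05) {
  pool <- c(ORACLE_AA, "-", "X")
  probs <- c(rep((1 - gapProb - ambigProb) / 20, 20), gapProb, ambigProb)
  seqs <- vapply(seq_len(nSeq), function(i)
    paste(sample(pool, nCol, replace = TRUE, prob = probs), collapse = ""),
    "")
  names(seqs) <- sprintf("seq%03d", seq_len(nSeq))
  seqs
}

# A reference row guaranteed to carry at least one standard residue.
randomReferenceRow <- function(nCol, gapProb = 0.15) {
  repeat {
    chars <- sample(c(ORACLE_AA, "-"), nCol, replace = TRUE,
                    prob = c(rep((1 - gapProb) / 20, 20), gapProb))
    if (any(chars != "-")) return(paste(chars, collapse = ""))
  }
}
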