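#' Per-column amino-acid frequency profiles
#'
#' Tallies (optionally weighted) counts of the 20 standard amino acids in
#' every alignment column. Gaps and ambiguity codes (B/Z/X/U/O) never enter
#' the counts; they contribute only to the column's gap fraction, so
#' frequencies are a distribution over amino acids actually observed. A
#' pseudocount, when positive, is added to all 20 residue counts before
#' frequencies are formed; it regularizes columns where the wild-type residue
#' is absent without changing the frequency ordering.
#'
#' Columns with no standard residue at all (all gap/ambiguous) are returned
#' with zero counts and flagged via \code{\link{allGapColumns}}; scoring
#' leaves their ratio undefined.
#'
#' @param msa an \code{\linkS4class{MSA}}.
#' @param pseudocount non-negative value added to each residue count at
#'   frequency time (default 0: raw frequencies).
#' @param weighting \code{"uniform"} (default; every row counts once) or
#'   \code{"position"} (position-based sequence weights damping redundant
#'   homologs; see \code{\link{sequenceWeights}}).
#' @param includeReference should the reference row contribute to the counts
#'   (default \code{TRUE}: the reference is one of the homologs)?
#' @param refId reference id; required when \code{includeReference = FALSE}.
#' @return a \code{\linkS4class{ColumnProfiles}}.
#' @examples
#' msa <- MSA(c(REF = "VV", a = "LV", b = "LV", c = "L-"))
#' p <- computeProfiles(msa)
#' profileFrequencies(p)
#' @export
computeProfiles <- function(msa, pseudocount = 0,
                            weighting = c("uniform", "position"),
                            includeReference = TRUE, refId = NULL) {
  stopifnot(is(msa, "MSA"))
  weighting <- match.arg(weighting)
  if (pseudocount < 0)
    stop("pseudocount must be non-negative")
  counted <- msa
  if (!includeReference) {
    if (is.null(refId))
      stop("refId is required when includeReference = FALSE")
    if (!(refId %in% names(msa)))
      stop(sprintf("unknown reference id '%s'", refId))
    keep <- setdiff(names(msa), refId)
    if (length(keep) < 1L)
      stop("no sequences left after excluding the reference")
    counted <- as(msa, "AAStringSet")[keep]
  }
  w <- if (weighting == "position" && length(counted) > 1L)
    henikoffWeights(counted) else stats::setNames(rep(1, length(counted)),
                                                  names(counted))
  mat <- as.matrix(counted)  # rows x columns, single characters
  nc <- ncol(mat)
  counts <- matrix(0, nrow = length(AA20), ncol = nc,
                   dimnames = list(AA20, NULL))
  for (aa in AA20)
    counts[aa, ] <- colSums(w * (mat == aa))
  nEff <- colSums(counts)
  missing <- !(mat %in% c(AA20))  # gaps and ambiguity codes
  dim(missing) <- dim(mat)
  gapFrac <- colSums(w * missing) / sum(w)
  nAllGap <- sum(nEff == 0)
  if (nAllGap > 0L)
    message(sprintf("%d column(s) contain no standard residue; flagged as all-gap",
                    nAllGap))
  new("ColumnProfiles", counts = counts, nEffective = nEff,
      gapFraction = gapFrac, pseudocount = pseudocount, weighting = weighting)
}

#' Position-based sequence weights
#'
#' Down-weights redundant homologs with the classic position-based scheme:
#' in each column a residue type shared by \eqn{k} of the sequences, among
#' \eqn{r} distinct types, contributes \eqn{1/(r k)} to each of those
#' sequences; a sequence's weight is its average contribution over the
#' columns where it has a standard residue. Weights are normalized to mean 1,
#' so uniform weighting is recovered when all sequences are identical.
#'
#' This is provided as an explicit option; profiling defaults to uniform
#' (raw) frequencies.
#'
#' @param msa an \code{\linkS4class{MSA}} (or \code{AAStringSet}).
#' @param scheme \code{"uniform"} returns all-ones; \code{"position"} the
#'   weights described above.
#' @return named numeric vector of weights, mean 1.
#' @export
sequenceWeights <- function(msa, scheme = c("uniform", "position")) {
  scheme <- match.arg(scheme)
  if (scheme == "uniform")
    return(stats::setNames(rep(1, length(msa)), names(msa)))
  henikoffWeights(msa)
}

henikoffWeights <- function(set) {
  mat <- as.matrix(set)
  n <- nrow(mat)
  contrib <- matrix(0, nrow = n, ncol = ncol(mat))
  informative <- matrix(FALSE, nrow = n, ncol = ncol(mat))
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    std <- col %in% AA20
    if (!any(std)) next
    tab <- table(col[std])
    r <- length(tab)
    contrib[std, j] <- 1 / (r * as.numeric(tab[col[std]]))
    informative[std, j] <- TRUE
  }
  ncols <- rowSums(informative)
  w <- ifelse(ncols > 0, rowSums(contrib) / pmax(ncols, 1L), 0)
  # rows with no standard residue anywhere get the average weight
  if (any(ncols == 0)) w[ncols == 0] <- mean(w[ncols > 0])
  w <- w / mean(w)
  stats::setNames(w, names(set))
}

#' Score reference positions by f(cons)/f(WT)
#'
#' For every residue of the ungapped reference, takes the column's frequency
#' profile and reports the wild-type residue, the consensus residue (the most
#' frequent standard amino acid), their frequencies \code{fWt} and
#' \code{fCons}, and the stabilization score \code{ratio = fCons / fWt}.
#'
#' Conventions: if the wild-type residue is among the residues tied for the
#' maximum frequency, the consensus \emph{is} the wild type (ratio 1, never
#' selected); otherwise ties break to the alphabetically first residue. If
#' \code{fWt} is 0 (wild-type residue absent from the column and no
#' pseudocount), the ratio is \code{+Inf}: such a position is maximally
#' non-consensus and exceeds every finite threshold. Columns flagged all-gap
#' (and reference positions whose residue is an ambiguity code) get
#' \code{NA} ratios, are excluded from selection, and are reported in the
#' panel's skipped-positions list.
#'
#' @param profiles \code{\linkS4class{ColumnProfiles}} computed from
#'   \code{msa}.
#' @param mapping \code{\linkS4class{ReferenceMapping}} for the same
#'   alignment.
#' @param msa the \code{\linkS4class{MSA}} itself (source of the wild-type
#'   residues).
#' @return a \code{\link[S4Vectors]{DataFrame}} with one row per reference
#'   residue in ascending \code{residueNumber} and columns
#'   \code{residueNumber}, \code{wtResidue}, \code{consensusResidue},
#'   \code{fWt}, \code{fCons}, \code{ratio}, \code{nEffective},
#'   \code{gapFraction}, \code{column}. Metadata records \code{refId} and
#'   \code{refLength}.
#' @examples
#' msa <- MSA(c(REF = "VA", h1 = "LA", h2 = "LA", h3 = "VA"))
#' sc <- scorePositions(computeProfiles(msa), mapReference(msa, "REF"), msa)
#' sc$ratio
#' @export
scorePositions <- function(profiles, mapping, msa) {
  stopifnot(is(profiles, "ColumnProfiles"),
            is(mapping, "ReferenceMapping"),
            is(msa, "MSA"))
  if (ncol(profiles@counts) != length(mapping@columnToResidue))
    stop("profiles and mapping disagree on the number of alignment columns")
  refChars <- strsplit(as.character(msa[[refId(mapping)]]), "",
                       fixed = TRUE)[[1L]]
  cols <- which(!is.na(mapping@columnToResidue))
  freqs <- profileFrequencies(profiles)
  n <- length(cols)
  wt <- refChars[cols]
  if (any(wt == GAP_CHAR))
    stop("internal inconsistency: reference gap at a mapped column")
  consensus <- character(n)
  fWt <- fCons <- ratio <- numeric(n)
  for (k in seq_len(n)) {
    j <- cols[k]
    if (profiles@nEffective[j] == 0 || !(wt[k] %in% AA20)) {
      consensus[k] <- NA_character_
      fWt[k] <- fCons[k] <- ratio[k] <- NA_real_
      next
    }
    f <- freqs[, j]
    fmax <- max(f)
    tied <- AA20[f >= fmax - 1e-12]
    consensus[k] <- if (wt[k] %in% tied) wt[k] else tied[1L]
    fWt[k] <- f[wt[k]]
    fCons[k] <- f[consensus[k]]
    ratio[k] <- if (consensus[k] == wt[k]) 1
                else if (fWt[k] == 0) Inf
                else fCons[k] / fWt[k]
  }
  nUndef <- sum(is.na(ratio))
  if (nUndef > 0L)
    warning(sprintf(
      "%d reference position(s) have undefined ratio (all-gap column or ambiguous wild-type residue); they will never be selected",
      nUndef))
  out <- DataFrame(residueNumber = mapping@columnToResidue[cols],
                   wtResidue = wt,
                   consensusResidue = consensus,
                   fWt = fWt, fCons = fCons, ratio = ratio,
                   nEffective = profiles@nEffective[cols],
                   gapFraction = profiles@gapFraction[cols],
                   column = cols)
  metadata(out) <- list(refId = refId(mapping), refLength = refLength(mapping))
  out
}

#' Write a position-score table as TSV
#'
#' Columns: \code{residue_number}, \code{wt_residue}, \code{consensus_residue},
#' \code{f_wt}, \code{f_cons}, \code{ratio}, \code{n_effective},
#' \code{gap_fraction}. Infinite ratios are serialized as the token
#' \code{"inf"}.
#'
#' @param scores result of \code{\link{scorePositions}}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeScoreTable <- function(scores, path) {
  df <- data.frame(residue_number = scores$residueNumber,
                   wt_residue = scores$wtResidue,
                   consensus_residue = scores$consensusResidue,
                   f_wt = scores$fWt,
                   f_cons = scores$fCons,
                   ratio = formatRatio(scores$ratio),
                   n_effective = scores$nEffective,
                   gap_fraction = scores$gapFraction,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Score an alignment in one call
#'
#' Convenience wrapper chaining \code{\link{mapReference}},
#' \code{\link{computeProfiles}} and \code{\link{scorePositions}}.
#'
#' @inheritParams computeProfiles
#' @param refId identifier of the wild-type reference record.
#' @return the score \code{DataFrame} of \code{\link{scorePositions}}.
#' @export
scoreAlignment <- function(msa, refId, pseudocount = 0,
                           weighting = c("uniform", "position"),
                           includeReference = TRUE) {
  mapping <- mapReference(msa, refId)
  profiles <- computeProfiles(msa, pseudocount = pseudocount,
                              weighting = weighting,
                              includeReference = includeReference,
                              refId = refId)
  scorePositions(profiles, mapping, msa)
}

#' @rdname ColumnProfiles-class
#' @export
setMethod("profileCounts", "ColumnProfiles", function(x) x@counts)

#' @rdname ColumnProfiles-class
#' @export
setMethod("profileFrequencies", "ColumnProfiles", function(x) {
  num <- x@counts + x@pseudocount
  den <- x@nEffective + 20 * x@pseudocount
  f <- sweep(num, 2L, den, "/")
  f[, den == 0] <- NA_real_
  f
})

#' @rdname ColumnProfiles-class
#' @export
setMethod("nEffective", "ColumnProfiles", function(x) x@nEffective)

#' @rdname ColumnProfiles-class
#' @export
setMethod("gapFraction", "ColumnProfiles", function(x) x@gapFraction)

#' @rdname ColumnProfiles-class
#' @export
setMethod("allGapColumns", "ColumnProfiles",
          function(x) which(x@nEffective == 0))

setMethod("show", "ColumnProfiles", function(object) {
  cat(sprintf(
    "ColumnProfiles: %d columns, %s weighting, pseudocount %g, %d all-gap\n",
    ncol(object@counts), object@weighting, object@pseudocount,
    sum(object@nEffective == 0)))
})
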