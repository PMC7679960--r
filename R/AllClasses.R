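#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom IRanges IRanges
NULL

#' Multiple sequence alignment of protein homologs
#'
#' An \code{MSA} is an \code{\link[Biostrings]{AAStringSet}} whose members all
#' have the same width (the alignment columns), with unique non-empty names
#' (the sequence identifiers), at least two members, residues upper-cased, and
#' \code{"-"} as the only gap character. Ambiguity codes B/Z/X/U/O are allowed
#' and treated as missing data by the profiling functions.
#'
#' Use \code{\link{readMSA}} or \code{\link{MSA}} to construct one; both
#' normalize \code{"."} gaps to \code{"-"} and upper-case lower-case residues.
#'
#' @seealso \code{\link{readMSA}}, \code{\link{mapReference}},
#'   \code{\link{computeProfiles}}
#' @export
setClass("MSA", contains = "AAStringSet")

setValidity("MSA", function(object) {
  msgs <- character(0)
  if (length(object) < 2L)
    msgs <- c(msgs, "an alignment needs at least 2 sequences")
  ids <- names(object)
  if (is.null(ids) || any(!nzchar(ids)))
    msgs <- c(msgs, "every record needs a non-empty id")
  else if (anyDuplicated(ids))
    msgs <- c(msgs, sprintf("duplicate sequence id(s): %s",
                            paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  w <- Biostrings::width(object)
  if (length(w) && any(w == 0L))
    msgs <- c(msgs, "empty sequence records are not allowed")
  if (length(unique(w)) > 1L) {
    bad <- ids[which(w != w[1L])[1L]]
    msgs <- c(msgs, sprintf(
      "ragged alignment: record '%s' has length %d, expected %d",
      bad, w[w != w[1L]][1L], w[1L]))
  }
  if (length(object)) {
    seen <- colSums(Biostrings::alphabetFrequency(object))
    bad <- setdiff(names(seen[seen > 0L]), AA_ALLOWED)
    if (length(bad))
      msgs <- c(msgs, sprintf("disallowed character(s) in alignment: %s",
                              paste(bad, collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' Mapping from alignment columns to reference residue numbers
#'
#' Records, for one reference row of an \code{\link{MSA}}, which alignment
#' column corresponds to which 1-based residue number of the ungapped
#' reference. Columns where the reference row carries a gap have no residue
#' number (\code{NA} in \code{columnToResidue}).
#'
#' @slot refId identifier of the reference record.
#' @slot columnToResidue integer vector, one entry per alignment column;
#'   the residue number at that column or \code{NA} where the reference is
#'   gapped.
#' @slot refLength number of residues in the ungapped reference.
#'
#' @seealso \code{\link{mapReference}}
#' @export
setClass("ReferenceMapping",
  representation(refId = "character",
                 columnToResidue = "integer",
                 refLength = "integer"))

setValidity("ReferenceMapping", function(object) {
  v <- object@columnToResidue
  obs <- v[!is.na(v)]
  if (is.unsorted(obs, strictly = TRUE))
    return("residue numbers must be strictly increasing along non-gap columns")
  if (!identical(as.integer(obs), seq_len(object@refLength)))
    return("mapped residue numbers must be exactly 1..refLength")
  TRUE
})

#' Per-column residue frequency profiles of an alignment
#'
#' Holds, for every alignment column, the (optionally weighted) counts of the
#' 20 standard amino acids, the effective count of standard residues, and the
#' fraction of rows that are gap or ambiguity code at that column. Frequencies
#' are computed over standard residues only: a gap is absence of evidence, not
#' a 21st residue.
#'
#' @slot counts 20 x n_columns matrix of weighted observed counts (rows in
#'   alphabetical amino-acid order); the pseudocount is \emph{not} folded in.
#' @slot nEffective per-column sum of observed counts.
#' @slot gapFraction per-column weighted fraction of gap/ambiguous rows.
#' @slot pseudocount value added to each of the 20 counts when frequencies
#'   are formed.
#' @slot weighting \code{"uniform"} or \code{"position"}.
#'
#' @seealso \code{\link{computeProfiles}}, \code{\link{profileFrequencies}}
#' @export
setClass("ColumnProfiles",
  representation(counts = "matrix",
                 nEffective = "numeric",
                 gapFraction = "numeric",
                 pseudocount = "numeric",
                 weighting = "character"))

setValidity("ColumnProfiles", function(object) {
  msgs <- character(0)
  if (!identical(rownames(object@counts), AA20))
    msgs <- c(msgs, "counts must have one row per standard amino acid")
  if (any(object@counts < 0))
    msgs <- c(msgs, "counts must be non-negative")
  nc <- ncol(object@counts)
  if (length(object@nEffective) != nc || length(object@gapFraction) != nc)
    msgs <- c(msgs, "nEffective and gapFraction must have one entry per column")
  if (max(abs(colSums(object@counts) - object@nEffective)) > 1e-6)
    msgs <- c(msgs, "nEffective must equal the column sums of counts")
  if (any(object@gapFraction < -1e-9 | object@gapFraction > 1 + 1e-9))
    msgs <- c(msgs, "gapFraction must lie in [0, 1]")
  if (object@pseudocount < 0)
    msgs <- c(msgs, "pseudocount must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' A designed mutant construct
#'
#' The result of applying a set of consensus substitutions to an ungapped
#' reference sequence: the mutated sequence together with the selection
#' threshold, the mutation table, and mutation-load statistics. The load is
#' reported as a percentage of the \emph{total} reference length (not of the
#' masked region), and rounded half-up to one decimal, which is also how the
#' construct inherits its name in a threshold sweep (e.g. \code{"xCT_20.2"}).
#'
#' @slot name construct name.
#' @slot threshold the f(cons)/f(WT) cutoff that produced the mutation set
#'   (\code{NA} when the construct was built from an explicit list).
#' @slot mutations \code{DataFrame} of substitutions sorted by residue number,
#'   with columns \code{notation}, \code{residueNumber}, \code{wtResidue},
#'   \code{newResidue} and, when derived from scores, \code{fWt}, \code{fCons},
#'   \code{ratio}.
#' @slot sequence the mutated sequence (ungapped, one character per residue).
#' @slot refLength length of the reference.
#' @slot mutationCount number of substitutions.
#' @slot mutationPercent 100 * mutationCount / refLength, rounded half-up to
#'   one decimal.
#'
#' @seealso \code{\link{buildConstruct}}, \code{\link{sweepThresholds}}
#' @export
setClass("ConstructDesign",
  representation(name = "character",
                 threshold = "numeric",
                 mutations = "DataFrame",
                 sequence = "character",
                 refLength = "integer",
                 mutationCount = "integer",
                 mutationPercent = "numeric"))

setValidity("ConstructDesign", function(object) {
  msgs <- character(0)
  if (nchar(object@sequence) != object@refLength)
    msgs <- c(msgs, "sequence length must equal refLength")
  if (object@mutationCount != nrow(object@mutations))
    msgs <- c(msgs, "mutationCount must equal the number of mutation rows")
  if (object@mutationPercent < 0 || object@mutationPercent > 100)
    msgs <- c(msgs, "mutationPercent must lie in [0, 100]")
  expect <- roundHalfUp(100 * object@mutationCount / object@refLength, 1L)
  if (abs(expect - object@mutationPercent) > 0.05)
    msgs <- c(msgs, "mutationPercent inconsistent with mutationCount/refLength")
  if (length(msgs)) msgs else TRUE
})

#' Summary of a construct panel
#'
#' Returned by \code{\link{writePanelReport}}: one summary row per construct,
#' sorted by descending threshold, plus the reference positions whose score
#' was undefined (all-gap alignment columns) and therefore never selectable.
#'
#' @slot constructs \code{DataFrame} with columns \code{construct},
#'   \code{threshold}, \code{mutation_count}, \code{mutation_percent}.
#' @slot skippedPositions integer residue numbers with undefined ratio.
#'
#' @export
setClass("PanelReport",
  representation(constructs = "DataFrame",
                 skippedPositions = "integer"))
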