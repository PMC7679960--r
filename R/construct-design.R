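#' Format and parse point-mutation notation
#'
#' Standard \code{"wtPOSnew"} notation, e.g. \code{"V123L"}: wild-type
#' residue, 1-based reference position, new residue.
#'
#' @param wtResidue,newResidue single amino-acid characters.
#' @param residueNumber 1-based reference position(s).
#' @return \code{formatMutation}: character vector of notations.
#'   \code{parseMutation}: \code{DataFrame} with columns \code{wtResidue},
#'   \code{residueNumber}, \code{newResidue}.
#' @examples
#' formatMutation("V", 123, "L")
#' parseMutation("V123L")
#' @export
formatMutation <- function(wtResidue, residueNumber, newResidue) {
  sprintf("%s%d%s", wtResidue, as.integer(residueNumber), newResidue)
}

#' @rdname formatMutation
#' @param notation character vector of \code{"wtPOSnew"} strings.
#' @export
parseMutation <- function(notation) {
  m <- regmatches(notation, regexec("^([A-Y])([0-9]+)([A-Y])$", notation))
  bad <- lengths(m) != 4L
  if (any(bad))
    stop(sprintf("malformed mutation notation: %s",
                 paste(notation[bad], collapse = ", ")))
  DataFrame(wtResidue = vapply(m, `[`, "", 2L),
            residueNumber = as.integer(vapply(m, `[`, "", 3L)),
            newResidue = vapply(m, `[`, "", 4L))
}

#' Read a region mask of eligible residue ranges
#'
#' A mask is a two-column TSV of 1-based inclusive (start, end) residue
#' intervals on the ungapped reference (typically the transmembrane
#' segments); \code{"#"} comment lines are allowed. Overlapping or adjacent
#' ranges are merged and the result is sorted. An empty file is an error: an
#' empty mask is ambiguous, and "no mask" already means the whole sequence.
#'
#' @param path path to the mask TSV.
#' @param refLength optional reference length to validate range ends against.
#' @return an \code{\link[IRanges]{IRanges}} of eligible positions.
#' @export
readMask <- function(path, refLength = NULL) {
  if (!file.exists(path))
    stop(sprintf("mask file not found: %s", path))
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep))
    stop(sprintf("mask file %s contains no ranges", path))
  rows <- strsplit(trimws(lines[keep]), "[ \t]+")
  lineNo <- which(keep)
  starts <- ends <- integer(length(rows))
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) < 2L || anyNA(suppressWarnings(
        as.integer(rows[[i]][1:2]))))
      stop(sprintf("mask line %d: expected two integers, got '%s'",
                   lineNo[i], lines[lineNo[i]]))
    starts[i] <- as.integer(rows[[i]][1L])
    ends[i] <- as.integer(rows[[i]][2L])
    if (starts[i] < 1L || starts[i] > ends[i])
      stop(sprintf("mask line %d: invalid range (%d, %d)",
                   lineNo[i], starts[i], ends[i]))
    if (!is.null(refLength) && ends[i] > refLength)
      stop(sprintf("mask line %d: end %d exceeds reference length %d",
                   lineNo[i], ends[i], refLength))
  }
  IRanges::reduce(IRanges(start = starts, end = ends))
}

maskContains <- function(mask, positions) {
  if (is.null(mask)) return(rep(TRUE, length(positions)))
  stopifnot(is(mask, "IRanges") || is(mask, "IntegerRanges"))
  IRanges::overlapsAny(IRanges(positions, positions), mask)
}

#' Select consensus mutations above a threshold
#'
#' Picks exactly the reference positions whose score ratio is
#' \emph{strictly} greater than the threshold, whose consensus residue
#' differs from the wild type, and which lie inside the region mask (the
#' whole sequence when \code{mask} is \code{NULL}). Positions with undefined
#' ratio (all-gap columns) are never selected; positions with infinite ratio
#' (wild-type residue absent, no pseudocount) exceed every finite threshold
#' and are always selected.
#'
#' @param scores score table from \code{\link{scorePositions}}.
#' @param threshold positive f(cons)/f(WT) cutoff (strict inequality).
#' @param mask optional \code{\link[IRanges]{IRanges}} of eligible residue
#'   ranges, or \code{NULL}.
#' @return \code{DataFrame} of mutations sorted by \code{residueNumber},
#'   with columns \code{notation}, \code{residueNumber}, \code{wtResidue},
#'   \code{newResidue}, \code{fWt}, \code{fCons}, \code{ratio}. An empty
#'   selection is a valid result.
#' @export
selectMutations <- function(scores, threshold, mask = NULL) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("threshold must be a single positive number")
  sel <- !is.na(scores$ratio) &
    scores$ratio > threshold &
    scores$consensusResidue != scores$wtResidue &
    maskContains(mask, scores$residueNumber)
  sel[is.na(sel)] <- FALSE
  hits <- scores[sel, , drop = FALSE]
  hits <- hits[order(hits$residueNumber), , drop = FALSE]
  out <- DataFrame(notation = formatMutation(hits$wtResidue,
                                             hits$residueNumber,
                                             hits$consensusResidue),
                   residueNumber = hits$residueNumber,
                   wtResidue = hits$wtResidue,
                   newResidue = hits$consensusResidue,
                   fWt = hits$fWt, fCons = hits$fCons, ratio = hits$ratio)
  out
}

#' Build a mutant construct from a reference and a mutation list
#'
#' Applies the substitutions to the ungapped reference and records the
#' mutation-load statistics: \code{mutationCount} and
#' \code{mutationPercent = 100 * mutationCount / refLength}, the latter
#' rounded half-up to one decimal (a 501-residue reference with 101
#' substitutions reports 20.2).
#'
#' @param reference ungapped reference sequence (single character string,
#'   \code{AAString}, or length-1 named character as from
#'   \code{\link{referenceSequence}}).
#' @param mutations \code{DataFrame}/data.frame with columns
#'   \code{wtResidue}, \code{residueNumber}, \code{newResidue} (as produced
#'   by \code{\link{selectMutations}} or \code{\link{parseMutation}}).
#' @param name construct name.
#' @param threshold the cutoff that produced the mutation set, or \code{NA}.
#' @return a \code{\linkS4class{ConstructDesign}}.
#' @examples
#' ref <- "MVLAVGLTKE"
#' d <- buildConstruct(ref, parseMutation(c("V2L", "K8R")), "demo")
#' constructSequence(d)
#' mutationPercent(d)
#' @export
buildConstruct <- function(reference, mutations, name = "construct",
                           threshold = NA_real_) {
  if (is(reference, "XString")) reference <- as.character(reference)
  stopifnot(is.character(reference), length(reference) == 1L)
  reference <- toupper(reference)
  if (grepl(GAP_CHAR, reference, fixed = TRUE))
    stop("reference must be ungapped")
  chars <- strsplit(reference, "", fixed = TRUE)[[1L]]
  refLen <- length(chars)
  mut <- as.data.frame(mutations)
  if (nrow(mut)) {
    if (anyDuplicated(mut$residueNumber)) {
      dup <- unique(mut$residueNumber[duplicated(mut$residueNumber)])
      stop(sprintf("duplicate mutation(s) at position(s): %s",
                   paste(dup, collapse = ", ")))
    }
    if (any(mut$residueNumber < 1L | mut$residueNumber > refLen))
      stop("mutation position outside the reference")
    found <- chars[mut$residueNumber]
    bad <- which(found != mut$wtResidue)
    if (length(bad))
      stop(sprintf(
        "reference mismatch at position %d: expected %s, reference has %s",
        mut$residueNumber[bad[1L]], mut$wtResidue[bad[1L]], found[bad[1L]]))
    if (any(mut$wtResidue == mut$newResidue))
      stop("a mutation must change the residue (wt == new)")
    chars[mut$residueNumber] <- mut$newResidue
    mut <- mut[order(mut$residueNumber), , drop = FALSE]
  }
  keep <- intersect(c("notation", "residueNumber", "wtResidue", "newResidue",
                      "fWt", "fCons", "ratio"), colnames(mut))
  mdf <- DataFrame(mut[, keep, drop = FALSE])
  if (!"notation" %in% colnames(mdf) && nrow(mdf))
    mdf$notation <- formatMutation(mdf$wtResidue, mdf$residueNumber,
                                   mdf$newResidue)
  new("ConstructDesign", name = name, threshold = as.numeric(threshold),
      mutations = mdf, sequence = paste(chars, collapse = ""),
      refLength = refLen, mutationCount = nrow(mdf),
      mutationPercent = roundHalfUp(100 * nrow(mdf) / refLen, 1L))
}

#' Sweep a list of thresholds into a graded construct panel
#'
#' Builds one construct per threshold (descending), each combining all
#' mutations whose ratio strictly exceeds that threshold inside the mask.
#' Constructs are named \code{"<prefix>_<mutation_percent>"} (e.g.
#' \code{"xCT_20.2"}), so the panel reads as a series of graded mutation
#' loads; \code{nameByThreshold = TRUE} names by the cutoff instead.
#' Duplicate thresholds are collapsed with a warning. Because selection uses
#' a strict inequality, the mutation set at a higher threshold is always a
#' subset of that at a lower one.
#'
#' @param scores score table from \code{\link{scorePositions}}.
#' @param thresholds numeric vector of positive cutoffs.
#' @param mask optional \code{\link[IRanges]{IRanges}} region mask.
#' @param reference ungapped reference sequence.
#' @param namePrefix prefix for construct names.
#' @param nameByThreshold name constructs \code{"<prefix>_t<threshold>"}
#'   instead of by mutation load.
#' @return list of \code{\linkS4class{ConstructDesign}}, sorted by
#'   descending threshold.
#' @export
sweepThresholds <- function(scores, thresholds, mask = NULL, reference,
                            namePrefix = "construct",
                            nameByThreshold = FALSE) {
  if (!length(thresholds))
    stop("at least one threshold is required")
  if (any(!is.finite(thresholds) & !is.infinite(thresholds)) ||
      any(thresholds <= 0, na.rm = TRUE) || anyNA(thresholds))
    stop("thresholds must be positive numbers")
  if (anyDuplicated(thresholds)) {
    warning("duplicate thresholds collapsed")
    thresholds <- unique(thresholds)
  }
  thresholds <- sort(thresholds, decreasing = TRUE)
  lapply(thresholds, function(t) {
    muts <- selectMutations(scores, t, mask)
    d <- buildConstruct(reference, muts, name = "tmp", threshold = t)
    d@name <- if (nameByThreshold)
      sprintf("%s_t%g", namePrefix, t)
    else
      sprintf("%s_%s", namePrefix, formatPercent(mutationPercent(d)))
    d
  })
}

#' Diff a construct against its reference
#'
#' Character-wise comparison recovering the exact substitution list; the
#' inverse of \code{\link{buildConstruct}}.
#'
#' @param design a \code{\linkS4class{ConstructDesign}}.
#' @param reference the ungapped reference sequence.
#' @return \code{DataFrame} with columns \code{notation},
#'   \code{residueNumber}, \code{wtResidue}, \code{newResidue}.
#' @export
diffConstruct <- function(design, reference) {
  if (is(reference, "XString")) reference <- as.character(reference)
  refChars <- strsplit(toupper(reference), "", fixed = TRUE)[[1L]]
  mutChars <- strsplit(constructSequence(design), "", fixed = TRUE)[[1L]]
  if (length(refChars) != length(mutChars))
    stop("construct and reference have different lengths")
  at <- which(refChars != mutChars)
  DataFrame(notation = formatMutation(refChars[at], at, mutChars[at]),
            residueNumber = at,
            wtResidue = refChars[at],
            newResidue = mutChars[at])
}

#' @rdname ConstructDesign-class
#' @export
setMethod("designName", "ConstructDesign", function(x) x@name)

#' @rdname ConstructDesign-class
#' @export
setMethod("designThreshold", "ConstructDesign", function(x) x@threshold)

#' @rdname ConstructDesign-class
#' @export
setMethod("mutations", "ConstructDesign", function(x) x@mutations)

#' @rdname ConstructDesign-class
#' @export
setMethod("constructSequence", "ConstructDesign", function(x) x@sequence)

#' @rdname ConstructDesign-class
#' @export
setMethod("mutationCount", "ConstructDesign", function(x) x@mutationCount)

#' @rdname ConstructDesign-class
#' @export
setMethod("mutationPercent", "ConstructDesign", function(x) x@mutationPercent)

setMethod("show", "ConstructDesign", function(object) {
  cat(sprintf(
    "ConstructDesign '%s': %d/%d residues mutated (%s%%), threshold %s\n",
    object@name, object@mutationCount, object@refLength,
    formatPercent(object@mutationPercent),
    ifelse(is.na(object@threshold), "-", format(object@threshold))))
  if (object@mutationCount)
    cat("  ", paste(utils::head(object@mutations$notation, 12L),
                    collapse = " "),
        if (object@mutationCount > 12L) "..." else "", "\n")
})
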