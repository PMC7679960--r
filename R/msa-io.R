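#' Construct an MSA from sequences in memory
#'
#' Normalizes a set of equal-length aligned protein sequences into an
#' \code{\linkS4class{MSA}}: residues are upper-cased (lower case is common in
#' masked alignments and accepted silently), \code{"."} gaps become \code{"-"},
#' and all alignment invariants are checked.
#'
#' @param x a named character vector, \code{AAStringSet} or \code{BStringSet}
#'   of aligned sequences.
#' @return an \code{\linkS4class{MSA}}.
#' @examples
#' msa <- MSA(c(ref = "AC-DE", hom1 = "ACGDE", hom2 = "ACGD-"))
#' ncol(as.matrix(msa))
#' @export
MSA <- function(x) {
  if (is(x, "XStringSet")) {
    ids <- names(x)
    x <- as.character(x)
    names(x) <- ids
  }
  if (!is.character(x))
    stop("'x' must be a character vector or XStringSet of aligned sequences")
  x <- chartr(".", "-", toupper(x))
  checkAlphabet(x)
  new("MSA", Biostrings::AAStringSet(x))
}

# Report the first disallowed character with record and position context,
# before handing off to AAStringSet (whose own alphabet error is less helpful).
checkAlphabet <- function(seqs) {
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[[i]], "", fixed = TRUE)[[1L]]
    bad <- which(!(chars %in% AA_ALLOWED))
    if (length(bad))
      stop(sprintf("disallowed character '%s' in record '%s' at column %d",
                   chars[bad[1L]], names(seqs)[i] %||% i, bad[1L]))
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a multiple sequence alignment
#'
#' Reads an aligned protein alignment in aligned-FASTA, Clustal or Stockholm
#' format (parsing by \pkg{Biostrings}) and validates it: all records must
#' have the same length, ids (the first whitespace-delimited token of a FASTA
#' header) must be unique, and only amino acids, ambiguity codes B/Z/X/U/O
#' and the gap characters \code{"-"}/\code{"."} are allowed. \code{"."} is
#' normalized to \code{"-"} and lower-case residues are up-cased.
#'
#' @param path path to the alignment file.
#' @param format one of \code{"fasta"}, \code{"clustal"}, \code{"stockholm"}.
#' @return an \code{\linkS4class{MSA}}.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">ref", "AC-DE", ">hom", "ACGDE"), fa)
#' readMSA(fa)
#' @export
readMSA <- function(path, format = c("fasta", "clustal", "stockholm")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop(sprintf("alignment file not found: %s", path))
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    if (!length(set))
      stop(sprintf("no sequences found in %s", path))
    names(set) <- vapply(strsplit(names(set), "[ \t]+"), `[`, "", 1L)
  } else {
    aln <- Biostrings::readAAMultipleAlignment(path, format = format)
    set <- as(aln, "AAStringSet")
  }
  seqs <- as.character(set)
  names(seqs) <- names(set)
  if (anyDuplicated(names(seqs)))
    stop(sprintf("duplicate sequence id(s): %s",
                 paste(unique(names(seqs)[duplicated(names(seqs))]),
                       collapse = ", ")))
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    off <- which(lens != lens[1L])[1L]
    stop(sprintf("ragged alignment: record '%s' has length %d, expected %d",
                 names(seqs)[off], lens[off], lens[1L]))
  }
  MSA(seqs)
}

#' Write an MSA as aligned FASTA
#'
#' \code{"-"} is the canonical gap on output; round-tripping through
#' \code{\link{readMSA}} recovers identical ids and residues.
#'
#' @param msa an \code{\linkS4class{MSA}}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeMSA <- function(msa, path) {
  stopifnot(is(msa, "MSA"))
  Biostrings::writeXStringSet(as(msa, "AAStringSet"), path, width = 60L)
  invisible(path)
}

#' Map alignment columns to reference residue numbers
#'
#' Establishes the coordinate system used by all scoring and design
#' functions: every non-gap column of the chosen reference row is assigned
#' the 1-based residue number of the ungapped reference (standard
#' mutation-notation convention).
#'
#' @param msa an \code{\linkS4class{MSA}}.
#' @param refId identifier of the reference record within the alignment.
#' @return a \code{\linkS4class{ReferenceMapping}}.
#' @examples
#' msa <- MSA(c(REF = "A-CD", hom = "AGCD"))
#' m <- mapReference(msa, "REF")
#' columnToResidue(m)   # NA at the reference's gap column
#' refLength(m)
#' @export
mapReference <- function(msa, refId) {
  stopifnot(is(msa, "MSA"))
  if (!(refId %in% names(msa)))
    stop(sprintf("unknown reference id '%s' (alignment has: %s%s)", refId,
                 paste(utils::head(names(msa), 5L), collapse = ", "),
                 if (length(msa) > 5L) ", ..." else ""))
  chars <- strsplit(as.character(msa[[refId]]), "", fixed = TRUE)[[1L]]
  nonGap <- chars != GAP_CHAR
  map <- rep(NA_integer_, length(chars))
  map[nonGap] <- seq_len(sum(nonGap))
  new("ReferenceMapping", refId = refId, columnToResidue = map,
      refLength = sum(nonGap))
}

#' Extract the ungapped reference sequence
#'
#' @param msa an \code{\linkS4class{MSA}}.
#' @param mapping a \code{\linkS4class{ReferenceMapping}} for \code{msa}.
#' @return single character string: the reference with gaps removed.
#' @export
referenceSequence <- function(msa, mapping) {
  stopifnot(is(msa, "MSA"), is(mapping, "ReferenceMapping"))
  gsub(GAP_CHAR, "", as.character(msa[[refId(mapping)]]), fixed = TRUE)
}

#' @rdname ReferenceMapping-class
#' @export
setMethod("refId", "ReferenceMapping", function(x) x@refId)

#' @rdname ReferenceMapping-class
#' @export
setMethod("refLength", "ReferenceMapping", function(x) x@refLength)

#' @rdname ReferenceMapping-class
#' @export
setMethod("columnToResidue", "ReferenceMapping", function(x) x@columnToResidue)

setMethod("show", "ReferenceMapping", function(object) {
  cat(sprintf("ReferenceMapping for '%s': %d residues over %d columns (%d gap)\n",
              object@refId, object@refLength, length(object@columnToResidue),
              sum(is.na(object@columnToResidue))))
})

setMethod("show", "MSA", function(object) {
  cat(sprintf("MSA with %d sequences x %d columns\n",
              length(object), Biostrings::width(object)[1L]))
  callNextMethod()
})
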