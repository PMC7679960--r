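#' Write an annotated alignment of reference and construct
#'
#' Emits the aligned reference row and the construct (in alignment
#' coordinates, reference gaps retained) in blocks of 60 columns, with a
#' marker line carrying \code{"*"} under exactly the columns whose reference
#' residue was mutated — a terminal-friendly, diff-able stand-in for
#' highlighting mutated positions in an alignment figure. Output is
#' byte-deterministic for fixed inputs.
#'
#' @param msa the \code{\linkS4class{MSA}} the design was derived from.
#' @param design a \code{\linkS4class{ConstructDesign}} built from this
#'   reference.
#' @param mapping the \code{\linkS4class{ReferenceMapping}} used for scoring.
#' @param path output path.
#' @param width columns per block (default 60).
#' @return invisibly, \code{path}.
#' @export
writeAnnotatedAlignment <- function(msa, design, mapping, path, width = 60L) {
  stopifnot(is(msa, "MSA"), is(design, "ConstructDesign"),
            is(mapping, "ReferenceMapping"))
  refAln <- strsplit(as.character(msa[[refId(mapping)]]), "",
                     fixed = TRUE)[[1L]]
  if (refLength(mapping) != design@refLength)
    stop("design and mapping disagree on the reference length")
  mutChars <- strsplit(constructSequence(design), "", fixed = TRUE)[[1L]]
  ctr <- columnToResidue(mapping)
  mutAln <- refAln
  mutAln[!is.na(ctr)] <- mutChars[ctr[!is.na(ctr)]]
  marker <- rep(" ", length(refAln))
  mutatedAt <- mutations(design)$residueNumber
  marker[which(!is.na(ctr))[match(mutatedAt, ctr[!is.na(ctr)])]] <- "*"
  labels <- c(refId(mapping), designName(design), "")
  pad <- max(nchar(labels)) + 2L
  labels <- formatC(labels, width = -pad)
  con <- file(path, open = "wt")
  on.exit(close(con))
  nBlocks <- ceiling(length(refAln) / width)
  for (b in seq_len(nBlocks)) {
    idx <- ((b - 1L) * width + 1L):min(b * width, length(refAln))
    writeLines(c(paste0(labels[1L], paste(refAln[idx], collapse = "")),
                 paste0(labels[2L], paste(mutAln[idx], collapse = "")),
                 paste0(labels[3L], paste(marker[idx], collapse = ""))),
               con)
    if (b < nBlocks) writeLines("", con)
  }
  invisible(path)
}

#' Write the construct-panel summary table
#'
#' TSV with columns \code{construct}, \code{threshold},
#' \code{mutation_count}, \code{mutation_percent}, one row per construct
#' sorted by descending threshold, and returns the corresponding
#' \code{\linkS4class{PanelReport}} including any reference positions whose
#' score was undefined (never selectable).
#'
#' @param panel non-empty list of \code{\linkS4class{ConstructDesign}}.
#' @param path output path.
#' @param skippedPositions integer residue numbers with undefined ratio
#'   (e.g. \code{scores$residueNumber[is.na(scores$ratio)]}).
#' @return a \code{\linkS4class{PanelReport}}.
#' @export
writePanelReport <- function(panel, path, skippedPositions = integer(0)) {
  if (!length(panel))
    stop("empty panel: nothing to report")
  stopifnot(all(vapply(panel, is, TRUE, "ConstructDesign")))
  ord <- order(vapply(panel, designThreshold, 0), decreasing = TRUE,
               na.last = TRUE)
  panel <- panel[ord]
  df <- data.frame(
    construct = vapply(panel, designName, ""),
    threshold = vapply(panel, designThreshold, 0),
    mutation_count = vapply(panel, mutationCount, 0L),
    mutation_percent = vapply(panel, function(d)
      formatPercent(mutationPercent(d)), ""),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  new("PanelReport", constructs = DataFrame(df),
      skippedPositions = as.integer(sort(unique(skippedPositions))))
}

#' Write the per-construct mutation table
#'
#' TSV with columns \code{construct}, \code{notation},
#' \code{residue_number}, \code{wt_residue}, \code{new_residue},
#' \code{f_wt}, \code{f_cons}, \code{ratio} (infinite ratios as the token
#' \code{"inf"}; frequency columns are \code{NA} for constructs built from
#' explicit mutation lists).
#'
#' @param panel list of \code{\linkS4class{ConstructDesign}} (or a single
#'   design).
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeMutationTable <- function(panel, path) {
  if (is(panel, "ConstructDesign")) panel <- list(panel)
  rows <- lapply(panel, function(d) {
    m <- as.data.frame(mutations(d))
    if (!nrow(m))
      return(NULL)
    data.frame(construct = designName(d),
               notation = m$notation,
               residue_number = m$residueNumber,
               wt_residue = m$wtResidue,
               new_residue = m$newResidue,
               f_wt = if ("fWt" %in% names(m)) m$fWt else NA_real_,
               f_cons = if ("fCons" %in% names(m)) m$fCons else NA_real_,
               ratio = formatRatio(
                 if ("ratio" %in% names(m)) m$ratio else NA_real_),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(df))
    df <- data.frame(construct = character(0), notation = character(0),
                     residue_number = integer(0), wt_residue = character(0),
                     new_residue = character(0), f_wt = numeric(0),
                     f_cons = numeric(0), ratio = character(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write construct sequences as ungapped FASTA
#'
#' One record per construct, header = construct name.
#'
#' @param panel list of \code{\linkS4class{ConstructDesign}} (or one design).
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeConstructFasta <- function(panel, path) {
  if (is(panel, "ConstructDesign")) panel <- list(panel)
  seqs <- Biostrings::AAStringSet(vapply(panel, constructSequence, ""))
  names(seqs) <- vapply(panel, designName, "")
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' @rdname PanelReport-class
#' @export
setMethod("panelConstructs", "PanelReport", function(x) x@constructs)

#' @rdname PanelReport-class
#' @export
setMethod("skippedPositions", "PanelReport", function(x) x@skippedPositions)

setMethod("show", "PanelReport", function(object) {
  cat(sprintf("PanelReport: %d construct(s), %d skipped position(s)\n",
              nrow(object@constructs), length(object@skippedPositions)))
  print(as.data.frame(object@constructs))
})
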