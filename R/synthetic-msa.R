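#' Generate a synthetic alignment with known column statistics
#'
#' Draws each non-reference row i.i.d.: at every column a gap is drawn first
#' with the column's \code{gapProbability}, otherwise a residue is drawn from
#' the column's distribution. Conditional on being non-gap, the per-column
#' residue distribution is therefore \emph{exactly} the one specified, which
#' makes every downstream score analytically predictable (see
#' \code{\link{expectedScores}}). A fixed \code{referenceSequence}, when
#' given, is installed verbatim as the first record with id \code{"REF"}.
#'
#' A single integer seed governs the whole alignment; the same configuration
#' and seed always reproduce a byte-identical alignment.
#'
#' @param columns list of column specifications; each a list with
#'   \code{distribution} (named numeric over standard amino acids, summing
#'   to 1) and optional \code{gapProbability} (default 0, must be < 1).
#' @param nSequences number of random homolog rows (>= 2, or >= 1 when a
#'   reference is supplied).
#' @param referenceSequence optional residue string (no gaps) of length
#'   \code{length(columns)} installed as row \code{"REF"}.
#' @param seed integer random seed.
#' @return an \code{\linkS4class{MSA}}.
#' @examples
#' msa <- generateMSA(list(list(distribution = c(L = 0.6, V = 0.4))),
#'                    nSequences = 10, referenceSequence = "V", seed = 1)
#' @export
generateMSA <- function(columns, nSequences, referenceSequence = NULL,
                        seed = 1L) {
  validateColumnSpecs(columns)
  if (!is.null(referenceSequence)) {
    referenceSequence <- toupper(referenceSequence)
    if (nchar(referenceSequence) != length(columns))
      stop(sprintf("reference length %d does not match %d column specs",
                   nchar(referenceSequence), length(columns)))
    if (grepl(GAP_CHAR, referenceSequence, fixed = TRUE))
      stop("referenceSequence must be ungapped")
  }
  minRows <- if (is.null(referenceSequence)) 2L else 1L
  if (nSequences < minRows)
    stop("too few sequences for a valid alignment")
  set.seed(as.integer(seed))
  mat <- matrix(GAP_CHAR, nrow = nSequences, ncol = length(columns))
  for (j in seq_along(columns)) {
    spec <- columns[[j]]
    gp <- spec$gapProbability %||% 0
    isGap <- stats::runif(nSequences) < gp
    nRes <- sum(!isGap)
    if (nRes > 0L)
      mat[!isGap, j] <- sample(names(spec$distribution), nRes,
                               replace = TRUE, prob = spec$distribution)
  }
  seqs <- apply(mat, 1L, paste, collapse = "")
  names(seqs) <- sprintf("S%04d", seq_len(nSequences))
  if (!is.null(referenceSequence))
    seqs <- c(REF = referenceSequence, seqs)
  MSA(seqs)
}

validateColumnSpecs <- function(columns) {
  if (!is.list(columns) || !length(columns))
    stop("'columns' must be a non-empty list of column specifications")
  for (j in seq_along(columns)) {
    spec <- columns[[j]]
    d <- spec$distribution
    if (is.null(d) || is.null(names(d)) || !all(names(d) %in% AA20))
      stop(sprintf("column %d: distribution must be named over standard amino acids", j))
    if (any(d < 0) || abs(sum(d) - 1) > 1e-9)
      stop(sprintf("column %d: probabilities must be non-negative and sum to 1", j))
    gp <- spec$gapProbability %||% 0
    if (gp < 0 || gp >= 1)
      stop(sprintf("column %d: gapProbability must lie in [0, 1)", j))
  }
  invisible(TRUE)
}

#' Analytic position scores for a synthetic configuration
#'
#' The scores a perfect (infinite-sample) profiler would report for an
#' alignment generated from these column specifications with the given
#' reference: per column, \code{fCons} is the largest specified probability,
#' \code{fWt} the reference residue's probability, and the ratio their
#' quotient — ignoring sampling noise and the single reference row. Uses the
#' same tie rule as \code{\link{scorePositions}} (wild type wins ties; else
#' alphabetical).
#'
#' @param columns list of column specifications (see
#'   \code{\link{generateMSA}}).
#' @param referenceSequence the reference residue string (required).
#' @return \code{DataFrame} with columns \code{residueNumber},
#'   \code{wtResidue}, \code{consensusResidue}, \code{fWt}, \code{fCons},
#'   \code{ratio}.
#' @examples
#' expectedScores(list(list(distribution = c(L = 0.6, V = 0.4))), "V")$ratio
#' @export
expectedScores <- function(columns, referenceSequence) {
  validateColumnSpecs(columns)
  if (is.null(referenceSequence))
    stop("a reference sequence is required")
  referenceSequence <- toupper(referenceSequence)
  wt <- strsplit(referenceSequence, "", fixed = TRUE)[[1L]]
  if (length(wt) != length(columns))
    stop("reference length does not match the number of column specs")
  n <- length(columns)
  consensus <- character(n)
  fWt <- fCons <- ratio <- numeric(n)
  for (j in seq_len(n)) {
    p <- stats::setNames(rep(0, length(AA20)), AA20)
    p[names(columns[[j]]$distribution)] <- columns[[j]]$distribution
    pmax_ <- max(p)
    tied <- AA20[p >= pmax_ - 1e-12]
    consensus[j] <- if (wt[j] %in% tied) wt[j] else tied[1L]
    fWt[j] <- p[wt[j]]
    fCons[j] <- p[consensus[j]]
    ratio[j] <- if (consensus[j] == wt[j]) 1
                else if (fWt[j] == 0) Inf
                else fCons[j] / fWt[j]
  }
  DataFrame(residueNumber = seq_len(n), wtResidue = wt,
            consensusResidue = consensus, fWt = fWt, fCons = fCons,
            ratio = ratio)
}

#' Read a synthetic-alignment configuration file
#'
#' YAML document with keys \code{n_sequences}, \code{seed}, optional
#' \code{reference_sequence}, and \code{columns}: a list of entries each
#' carrying a \code{distribution} map (amino acid to probability) and an
#' optional \code{gap_probability}.
#'
#' @param path path to the YAML config.
#' @return list with elements \code{columns}, \code{nSequences},
#'   \code{referenceSequence}, \code{seed}, ready to splice into
#'   \code{\link{generateMSA}}.
#' @export
readSyntheticConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$n_sequences) || is.null(cfg$columns))
    stop("config must define n_sequences and columns")
  columns <- lapply(cfg$columns, function(col) {
    list(distribution = unlist(col$distribution),
         gapProbability = col$gap_probability %||% 0)
  })
  validateColumnSpecs(columns)
  list(columns = columns,
       nSequences = as.integer(cfg$n_sequences),
       referenceSequence = cfg$reference_sequence,
       seed = as.integer(cfg$seed %||% 1L))
}
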