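# Shared alphabet constants and small numeric helpers.

# The 20 standard amino acids, alphabetical (the tie-break order).
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Ambiguity / non-standard codes accepted on input but treated as missing
# when profiling (they cannot be assigned to a single standard residue).
AA_AMBIGUOUS <- c("B", "Z", "X", "U", "O")

GAP_CHAR <- "-"

AA_ALLOWED <- c(AA20, AA_AMBIGUOUS, GAP_CHAR)

#' Round half away from zero
#'
#' Base \code{round()} rounds half to even; construct labels use conventional
#' half-up rounding so that e.g. a 20.15\% load prints as 20.2.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return \code{x} rounded with ties going away from zero.
#' @keywords internal
roundHalfUp <- function(x, digits = 1L) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Format a mutation-load percentage with one decimal, half-up ("14.2", "0.0").
formatPercent <- function(x) {
  sprintf("%.1f", roundHalfUp(x, 1L))
}

# Serialize a ratio column for TSV output: +Inf -> "inf", NA -> "NA".
formatRatio <- function(r) {
  out <- ifelse(is.infinite(r), "inf", format(r, trim = TRUE, digits = 15))
  out[is.na(r)] <- "NA"
  out
}
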