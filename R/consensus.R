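#' The pCht/StSat satellite consensus
#'
#' The 32 bp consensus of the subterminal satellite unit (pCht, also called
#' StSat) that makes up the heterochromatic caps of African great ape
#' chromosome ends.
#'
#' @return Upper-case DNA string of length 32.
#' @export
#' @examples
#' nchar(stcap_consensus())
stcap_consensus <- function() {
  "GATATTTCCATGTTTATACAGATAGCGGTGTA"
}

#' Consensus matching model for unit detection
#'
#' Bundles the consensus sequence with the acceptance threshold used by
#' [find_units()]. A candidate occurrence is accepted when more than
#' `min_match_fraction` of the consensus positions are matched in its best
#' alignment; equivalently, the number of matched consensus bases must
#' exceed `floor(min_match_fraction * length)` (for the default 32-mer at
#' 0.90 that is "more than 28 bp", i.e. at least 29 matches).
#'
#' @param sequence Consensus DNA string (ACGT only).
#' @param min_match_fraction Minimum matched fraction of consensus
#'   positions, strict lower bound. Default 0.90.
#' @return An object of class `stcap_consensus` with fields `sequence`,
#'   `length`, `min_match_fraction`, `min_match_bp` (the strict ">" bound
#'   on matched bp) and `max_edits` (the implied edit-distance budget).
#' @export
#' @examples
#' cons <- consensus_model()
#' cons$min_match_bp  # 28: hits must match more than 28 of 32 bp
consensus_model <- function(sequence = stcap_consensus(),
                            min_match_fraction = 0.90) {
  sequence <- toupper(sequence)
  if (!grepl("^[ACGT]+$", sequence)) {
    stop("consensus must contain only A, C, G, T")
  }
  if (min_match_fraction <= 0 || min_match_fraction > 1) {
    stop("min_match_fraction must be in (0, 1]")
  }
  len <- nchar(sequence)
  # strict ">" bound; a min_match_fraction of 1 means an exact match
  min_match_bp <- min(floor(min_match_fraction * len), len - 1L)
  structure(
    list(
      sequence = sequence,
      length = len,
      min_match_fraction = min_match_fraction,
      min_match_bp = min_match_bp,
      max_edits = len - (min_match_bp + 1L)
    ),
    class = "stcap_consensus"
  )
}

#' @export
print.stcap_consensus <- function(x, ...) {
  cat(sprintf(
    "satellite consensus (%d bp): %s\n  accept: > %d matched bp (fraction > %.2f), edit budget %d\n",
    x$length, x$sequence, x$min_match_bp, x$min_match_fraction, x$max_edits
  ))
  invisible(x)
}
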