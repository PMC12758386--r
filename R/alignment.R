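# Center-star multiple alignment of SD-spacer copies.

#' Length-filter and align spacer copies
#'
#' Keeps copies whose raw length exceeds `min_length_fraction` of the
#' modal full length, then builds a center-star progressive alignment:
#' the center is the sequence with the highest mean pairwise identity to
#' the others, every sequence is globally aligned to the center, and the
#' pairwise gap patterns are merged column-wise. For near-identical
#' copies (the spacer regime) this is within the classical center-star
#' bound of the optimal sum-of-pairs alignment, and substitution-only
#' input round-trips with zero gap columns.
#'
#' @param sequences Named character vector or `DNAStringSet` of spacer
#'   copies (>= 2 after filtering).
#' @param min_length_fraction Keep sequences longer than this fraction
#'   of the modal length (default 0.90).
#' @return `DNAStringSet` of equal-width aligned sequences, with the
#'   kept member names; attribute `dropped` lists filtered-out members.
#' @export
align_spacers <- function(sequences, min_length_fraction = 0.90) {
  nm <- names(sequences)
  seqs <- toupper(as.character(sequences))
  names(seqs) <- nm
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    names(seqs) <- sprintf("seq%03d", seq_along(seqs))
  }
  lens <- nchar(seqs)
  tab <- table(lens)
  # modal full length; ties resolve to the longest candidate
  modal <- max(as.integer(names(tab)[tab == max(tab)]))
  keep <- lens > min_length_fraction * modal
  dropped <- names(seqs)[!keep]
  seqs <- seqs[keep]
  if (length(seqs) < 2L) {
    stop("fewer than 2 spacer copies pass the >", min_length_fraction,
         " x modal-length filter")
  }
  n <- length(seqs)

  # pairwise identities for center choice; equal-length pairs are scored
  # by exact column match, unequal by global alignment
  pid <- matrix(1, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      pid[i, j] <- pid[j, i] <- pair_identity(seqs[i], seqs[j])
    }
  }
  center <- which.max(rowMeans(pid))

  # substitution-only fast path: equal lengths and high identity mean
  # no alignment would open a gap (gap open 4 > 2x mismatch), so the
  # inputs are already column-aligned
  if (length(unique(nchar(seqs))) == 1L && min(pid[center, ]) > 0.5) {
    out <- Biostrings::DNAStringSet(seqs)
    attr(out, "dropped") <- dropped
    attr(out, "center") <- names(seqs)[center]
    return(out)
  }

  # align everything to the center and merge gap patterns
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  pats <- Biostrings::DNAStringSet(seqs[-center])
  pa <- Biostrings::pairwiseAlignment(
    pattern = pats, subject = Biostrings::DNAString(seqs[[center]]),
    type = "global", substitutionMatrix = submat,
    gapOpening = 4, gapExtension = 1
  )
  al_center <- as.character(Biostrings::alignedSubject(pa))
  al_other <- as.character(Biostrings::alignedPattern(pa))

  # master gap profile for the center: at each center position, the
  # maximum insertion length seen in any pairwise alignment
  center_len <- nchar(seqs[[center]])
  max_ins <- integer(center_len + 1L) # insertions before center pos i (1-based), last = after end
  parsed <- vector("list", length(al_center))
  for (k in seq_along(al_center)) {
    p <- parse_center_alignment(al_center[k], al_other[k], center_len)
    parsed[[k]] <- p
    max_ins <- pmax(max_ins, p$ins_len)
  }

  build_row <- function(ins_seqs, base_chars) {
    # ins_seqs: character vector length center_len+1 of inserted text
    # base_chars: character vector length center_len (may contain "-")
    out <- character(2L * center_len + 1L)
    for (i in seq_len(center_len + 1L)) {
      pad <- max_ins[i] - nchar(ins_seqs[i])
      out[2L * i - 1L] <- paste0(ins_seqs[i], strrep("-", pad))
      if (i <= center_len) out[2L * i] <- base_chars[i]
    }
    paste(out, collapse = "")
  }

  rows <- character(n)
  names(rows) <- names(seqs)
  center_chars <- strsplit(seqs[[center]], "")[[1]]
  rows[center] <- build_row(rep("", center_len + 1L), center_chars)
  idx <- setdiff(seq_len(n), center)
  for (k in seq_along(idx)) {
    p <- parsed[[k]]
    rows[idx[k]] <- build_row(p$ins_seq, p$base_chars)
  }
  out <- Biostrings::DNAStringSet(rows)
  attr(out, "dropped") <- dropped
  attr(out, "center") <- names(seqs)[center]
  out
}

# identity of the best global alignment of two sequences, as matched
# bases / alignment columns; exact-column fast path for equal lengths
pair_identity <- function(a, b) {
  if (nchar(a) == nchar(b)) {
    ra <- charToRaw(a); rb <- charToRaw(b)
    return(sum(ra == rb) / length(ra))
  }
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(a), subject = Biostrings::DNAString(b),
    type = "global", substitutionMatrix = submat,
    gapOpening = 4, gapExtension = 1
  )
  s1 <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s2 <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  sum(s1 == s2 & s1 != "-") / length(s1)
}

# decompose a pairwise alignment against the center into: per-center-
# position base characters for the other sequence (with "-" for center
# bases deleted in it) and inserted text before each center position
parse_center_alignment <- function(al_center, al_other, center_len) {
  ca <- strsplit(al_center, "")[[1]]
  oa <- strsplit(al_other, "")[[1]]
  ins_seq <- rep("", center_len + 1L)
  base_chars <- character(center_len)
  pos <- 0L
  for (i in seq_along(ca)) {
    if (ca[i] == "-") {
      ins_seq[pos + 1L] <- paste0(ins_seq[pos + 1L], oa[i])
    } else {
      pos <- pos + 1L
      base_chars[pos] <- oa[i]
    }
  }
  list(ins_seq = ins_seq, base_chars = base_chars,
       ins_len = nchar(ins_seq))
}
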