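# Variant signatures: a unit's ordered list of differences from the
# consensus. Canonical text form, one token per edit joined by ",":
#   SUB  "<pos><ref>><alt>"   e.g. "15T>C"
#   DEL  "<pos>del<ref>"      e.g. "3delT"
#   INS  "<pos>ins<alt>"      insertion immediately before consensus <pos>
# Positions are 1-based consensus coordinates; tokens are sorted by
# position (ties: DEL < SUB < INS). The empty string is the consensus
# itself.

#' Canonical signature string from an edit table
#'
#' @param edits data.frame with columns `pos` (1-based consensus
#'   position), `class` (`"SUB"`, `"DEL"` or `"INS"`), `ref`, `alt`.
#' @return A single canonical signature string (`""` for no edits).
#' @export
canonical_signature <- function(edits) {
  if (is.null(edits) || nrow(edits) == 0L) return("")
  rank <- c(DEL = 1L, SUB = 2L, INS = 3L)
  ord <- order(edits$pos, rank[edits$class])
  edits <- edits[ord, , drop = FALSE]
  tok <- character(nrow(edits))
  for (i in seq_len(nrow(edits))) {
    tok[i] <- switch(edits$class[i],
      SUB = sprintf("%d%s>%s", edits$pos[i], edits$ref[i], edits$alt[i]),
      DEL = sprintf("%ddel%s", edits$pos[i], edits$ref[i]),
      INS = sprintf("%dins%s", edits$pos[i], edits$alt[i]),
      stop("unknown edit class: ", edits$class[i])
    )
  }
  paste(tok, collapse = ",")
}

#' Parse a canonical signature string back into an edit table
#'
#' Inverse of [canonical_signature()].
#'
#' @param signature Canonical signature string.
#' @return data.frame with columns `pos`, `class`, `ref`, `alt`.
#' @export
parse_signature <- function(signature) {
  empty <- data.frame(
    pos = integer(), class = character(),
    ref = character(), alt = character()
  )
  if (is.na(signature) || !nzchar(signature)) return(empty)
  toks <- strsplit(signature, ",", fixed = TRUE)[[1]]
  out <- lapply(toks, function(t) {
    if (grepl("del", t, fixed = TRUE)) {
      m <- regmatches(t, regexec("^([0-9]+)del([ACGTN]+)$", t))[[1]]
      data.frame(pos = as.integer(m[2]), class = "DEL", ref = m[3], alt = "")
    } else if (grepl("ins", t, fixed = TRUE)) {
      m <- regmatches(t, regexec("^([0-9]+)ins([ACGTN]+)$", t))[[1]]
      data.frame(pos = as.integer(m[2]), class = "INS", ref = "", alt = m[3])
    } else {
      m <- regmatches(t, regexec("^([0-9]+)([ACGTN])>([ACGTN])$", t))[[1]]
      data.frame(pos = as.integer(m[2]), class = "SUB", ref = m[3], alt = m[4])
    }
  })
  do.call(rbind, out)
}

#' Apply a signature to the consensus
#'
#' Builds the concrete unit sequence carrying the edits described by a
#' signature. Used by the simulator to emit satellite variants.
#'
#' @param consensus Consensus DNA string.
#' @param signature Canonical signature string or edit table.
#' @return The edited sequence as a character string.
#' @export
apply_signature <- function(consensus, signature) {
  edits <- if (is.character(signature)) parse_signature(signature) else signature
  chars <- strsplit(consensus, "")[[1]]
  if (nrow(edits) == 0L) return(consensus)
  # apply right-to-left so earlier positions stay valid
  ord <- order(edits$pos, decreasing = TRUE)
  # inserted text attaches before `pos`; track per-slot prefixes
  ins_before <- rep("", length(chars) + 1L)
  for (i in ord) {
    p <- edits$pos[i]
    cl <- edits$class[i]
    if (cl == "SUB") {
      if (chars[p] != edits$ref[i]) stop("signature ref mismatch at ", p)
      chars[p] <- edits$alt[i]
    } else if (cl == "DEL") {
      if (chars[p] != substr(edits$ref[i], 1, 1)) stop("signature ref mismatch at ", p)
      chars[p] <- ""
    } else if (cl == "INS") {
      ins_before[p] <- paste0(edits$alt[i], ins_before[p])
    }
  }
  out <- character(0)
  for (p in seq_along(chars)) {
    out <- c(out, ins_before[p], chars[p])
  }
  paste0(paste(out, collapse = ""), ins_before[length(chars) + 1L])
}

#' Left-normalize a signature against the consensus
#'
#' Indels inside runs of identical bases are ambiguous (deleting either C
#' of a CC run gives the same sequence). This shifts DEL and INS edits as
#' far left as possible, so signatures from different alignment paths
#' collapse to one canonical form.
#'
#' @param signature Canonical signature string or edit table.
#' @param consensus Consensus DNA string.
#' @return Normalized canonical signature string.
#' @export
normalize_signature <- function(signature, consensus) {
  edits <- if (is.character(signature)) parse_signature(signature) else signature
  if (nrow(edits) == 0L) return("")
  for (i in seq_len(nrow(edits))) {
    cl <- edits$class[i]
    p <- edits$pos[i]
    if (cl == "DEL" && nchar(edits$ref[i]) == 1L) {
      while (p > 1L &&
             substr(consensus, p - 1L, p - 1L) == edits$ref[i] &&
             !any(edits$pos[-i] == p - 1L)) {
        p <- p - 1L
      }
      edits$pos[i] <- p
    } else if (cl == "INS") {
      s <- edits$alt[i]
      n <- nchar(s)
      while (p > 1L &&
             substr(consensus, p - 1L, p - 1L) == substr(s, n, n) &&
             !any(edits$pos[-i] == p - 1L)) {
        s <- paste0(substr(s, n, n), substr(s, 1L, n - 1L))
        p <- p - 1L
      }
      edits$pos[i] <- p
      edits$alt[i] <- s
    }
  }
  canonical_signature(edits)
}

# Extract the edit table, matched-base count and column count from a pair
# of aligned strings (consensus row may contain "-" for deletions ... the
# unit row "-" marks a deleted consensus base). Gap conventions:
#   consensus gap  -> INS (bases present in the unit only)
#   unit gap       -> DEL (consensus base missing from the unit)
alignment_edits <- function(aligned_consensus, aligned_unit) {
  ca <- strsplit(aligned_consensus, "")[[1]]
  ua <- strsplit(aligned_unit, "")[[1]]
  stopifnot(length(ca) == length(ua))
  pos <- 0L
  edits <- list()
  matched <- 0L
  i_ins <- NULL
  for (i in seq_along(ca)) {
    if (ca[i] == "-") {
      # insertion relative to consensus, attaches before pos+1
      edits[[length(edits) + 1L]] <- data.frame(
        pos = pos + 1L, class = "INS", ref = "", alt = ua[i]
      )
    } else {
      pos <- pos + 1L
      if (ua[i] == "-") {
        edits[[length(edits) + 1L]] <- data.frame(
          pos = pos, class = "DEL", ref = ca[i], alt = ""
        )
      } else if (ua[i] == ca[i]) {
        matched <- matched + 1L
      } else {
        edits[[length(edits) + 1L]] <- data.frame(
          pos = pos, class = "SUB", ref = ca[i], alt = ua[i]
        )
      }
    }
  }
  ed <- if (length(edits)) do.call(rbind, edits) else
    data.frame(pos = integer(), class = character(), ref = character(), alt = character())
  # merge consecutive INS at the same position into one token
  if (nrow(ed) > 1L) {
    ins <- ed$class == "INS"
    if (any(ins)) {
      by_pos <- split(ed[ins, , drop = FALSE], ed$pos[ins])
      merged <- do.call(rbind, lapply(by_pos, function(g) {
        data.frame(pos = g$pos[1], class = "INS", ref = "",
                   alt = paste(g$alt, collapse = ""))
      }))
      ed <- rbind(ed[!ins, , drop = FALSE], merged)
    }
  }
  list(
    edits = ed,
    signature = canonical_signature(ed),
    matched = matched,
    columns = length(ca)
  )
}

# Globally align a unit string to the consensus with unit edit costs and
# return its signature/matched-count. Vectorised over `units` by unique
# string (detected hits repeat heavily in tandem arrays).
align_units_to_consensus <- function(units, consensus) {
  uniq <- unique(units)
  res <- vector("list", length(uniq))
  names(res) <- uniq
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 0, mismatch = -1)
  for (u in uniq) {
    if (u == consensus) {
      res[[u]] <- list(signature = "", matched = nchar(consensus),
                       columns = nchar(consensus), edits = 0L)
      next
    }
    pa <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAString(u),
      subject = Biostrings::DNAString(consensus),
      type = "global",
      substitutionMatrix = submat,
      gapOpening = 0, gapExtension = 1
    )
    al <- alignment_edits(
      as.character(Biostrings::alignedSubject(pa)),
      as.character(Biostrings::alignedPattern(pa))
    )
    al$edits <- -as.integer(Biostrings::score(pa))
    al$signature <- normalize_signature(al$signature, consensus)
    res[[u]] <- al
  }
  res[units]
}
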