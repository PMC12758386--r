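# Satellite unit detection and annotation.

# For hits with edits, evaluate every window extension (0..budget bp on
# each side) and keep the best by identity, then leftmost start, then
# longest window. Results are cached on the local sequence context, so
# tandem repeats of the same variant are evaluated once.
canonical_rewindow <- function(h, seq_chr, consensus) {
  budget <- consensus$max_edits
  if (budget == 0L) return(h)
  n_seq <- nchar(seq_chr)
  imperfect <- which(h$identity < 1)
  if (!length(imperfect)) return(h)
  # a narrowest-range hit may be trimmed by up to the edit budget plus
  # the bases a wider window would add as insertions
  L <- consensus$length
  pad <- pmax(L + budget - (h$end[imperfect] - h$start[imperfect]), budget)
  ctx_start <- pmax(h$start[imperfect] - pad, 0L)
  ctx_end <- pmin(h$end[imperfect] + pad, n_seq)
  off_l <- h$start[imperfect] - ctx_start
  off_r <- ctx_end - h$end[imperfect]
  ctx <- substring(seq_chr, ctx_start + 1L, ctx_end)
  key <- paste(ctx, off_l, off_r, h$strand[imperfect], sep = "\r")
  first <- !duplicated(key)
  choice <- new.env(parent = emptyenv())
  for (i in which(first)) {
    combos <- expand.grid(ds = 0:off_l[i], de = 0:off_r[i])
    combos <- combos[combos$ds + combos$de <= pad[i], , drop = FALSE]
    strs <- substring(ctx[i], off_l[i] - combos$ds + 1L,
                      nchar(ctx[i]) - off_r[i] + combos$de)
    idx <- imperfect[i]
    strand <- h$strand[idx]
    oriented <- if (strand == "+") strs else
      vapply(strs, reverse_complement, character(1))
    al <- align_units_to_consensus(oriented, consensus$sequence)
    ident <- vapply(al, function(x) x$matched / x$columns, numeric(1))
    edits <- vapply(al, function(x) x$edits, integer(1))
    wid <- nchar(strs)
    # leftmost start on forward coordinates = largest ds
    best <- order(-ident, -combos$ds, edits, -wid)[1]
    assign(key[i], list(ds = combos$ds[best], de = combos$de[best],
                        al = al[[best]]), envir = choice)
  }
  for (i in seq_along(imperfect)) {
    ch <- get(key[i], envir = choice)
    idx <- imperfect[i]
    h$start[idx] <- h$start[idx] - ch$ds
    h$end[idx] <- h$end[idx] + ch$de
    h$hit[idx] <- substring(seq_chr, h$start[idx] + 1L, h$end[idx])
    h$matched[idx] <- ch$al$matched
    h$columns[idx] <- ch$al$columns
    h$signature[idx] <- ch$al$signature
    h$identity[idx] <- ch$al$matched / ch$al$columns
  }
  h
}

# align hit strings (oriented to the forward consensus) and attach
# matched/columns/signature/identity columns
type_hits <- function(h, consensus_seq) {
  aligned_str <- ifelse(h$strand == "+", h$hit,
                        vapply(h$hit, reverse_complement, character(1)))
  al <- align_units_to_consensus(aligned_str, consensus_seq)
  h$matched <- vapply(al, function(x) x$matched, integer(1))
  h$columns <- vapply(al, function(x) x$columns, integer(1))
  h$signature <- vapply(al, function(x) x$signature, character(1))
  h$identity <- h$matched / h$columns
  h
}

#' Detect satellite units against the consensus
#'
#' Scans a sequence for occurrences of the satellite consensus on both
#' strands, using exact-seeded approximate matching (edit distance up to
#' the consensus edit budget) followed by global re-alignment of each
#' candidate to type its variant signature. A hit is accepted when more
#' than `min_match_fraction` of the consensus positions are matched
#' (for the packaged 32-mer at 0.90: more than 28 bp). Overlapping hits
#' are resolved greedily by identity (then leftmost start).
#'
#' `N` bases never match; candidates with more than 10% `N` are
#' rejected.
#'
#' @param sequence DNA string (character or `DNAString`), ACGT/N.
#' @param consensus A [consensus_model()] (or a plain DNA string, which
#'   is wrapped with the default threshold).
#' @param arm Arm identifier to record in the output.
#' @param both_strands Also scan the reverse strand (default TRUE).
#' @return data.frame of units sorted by start: `arm`, `start`, `end`
#'   (0-based half-open), `strand`, `signature`, `identity` (matched
#'   bases / alignment columns), `matched`.
#' @export
find_units <- function(sequence, consensus = consensus_model(), arm = "seq",
                       both_strands = TRUE) {
  if (is.character(consensus)) consensus <- consensus_model(consensus)
  stopifnot(inherits(consensus, "stcap_consensus"))
  seq_chr <- toupper(as.character(sequence))
  empty <- data.frame(
    arm = character(), start = integer(), end = integer(),
    strand = character(), signature = character(),
    identity = numeric(), matched = integer()
  )
  if (!nzchar(seq_chr)) return(empty)
  if (!grepl("^[ACGTN]+$", seq_chr)) stop("sequence must be ACGT/N only")

  subject <- Biostrings::DNAString(seq_chr)
  hits <- list()
  strands <- if (both_strands) c("+", "-") else "+"
  for (strand in strands) {
    pat <- if (strand == "+") consensus$sequence else
      reverse_complement(consensus$sequence)
    mp <- Biostrings::matchPattern(
      pat, subject,
      max.mismatch = consensus$max_edits, with.indels = TRUE, fixed = TRUE
    )
    if (length(mp) == 0L) next
    df <- data.frame(
      start = Biostrings::start(mp) - 1L,
      end = Biostrings::end(mp),
      strand = strand,
      hit = as.character(mp)
    )
    hits[[strand]] <- df
  }
  if (!length(hits)) return(empty)
  h <- do.call(rbind, hits)
  rownames(h) <- NULL

  # reject N-rich candidates (N also never matches in the alignment)
  n_frac <- vapply(gregexpr("N", h$hit, fixed = TRUE), function(g)
    if (g[1] == -1L) 0L else length(g), integer(1)) / nchar(h$hit)
  h <- h[n_frac <= 0.10, , drop = FALSE]
  if (nrow(h) == 0L) return(empty)

  h <- type_hits(h, consensus$sequence)
  # canonical windows: matchPattern reports the narrowest matching
  # range, representing terminal variation as truncation; re-window
  # every imperfect hit over all left/right extensions within the edit
  # budget and keep the best (identity desc, leftmost, longest)
  h <- canonical_rewindow(h, seq_chr, consensus)
  h <- h[h$matched > consensus$min_match_bp, , drop = FALSE]
  h <- h[!duplicated(h[, c("start", "end", "strand")]), , drop = FALSE]
  if (nrow(h) == 0L) return(empty)

  # greedy non-overlap resolution: identity desc, then leftmost, then
  # longest, then strand for full determinism
  h <- h[order(-h$identity, h$start, -(h$end - h$start), h$strand), , drop = FALSE]
  occupied <- logical(nchar(seq_chr))
  keep <- logical(nrow(h))
  for (i in seq_len(nrow(h))) {
    span <- (h$start[i] + 1L):h$end[i]
    if (!any(occupied[span])) {
      keep[i] <- TRUE
      occupied[span] <- TRUE
    }
  }
  h <- h[keep, , drop = FALSE]
  h <- h[order(h$start), , drop = FALSE]
  out <- data.frame(
    arm = arm, start = h$start, end = h$end, strand = h$strand,
    signature = h$signature, identity = h$identity, matched = h$matched
  )
  rownames(out) <- NULL
  out
}

#' Tally variant signatures genome-wide
#'
#' Counts each canonical variant signature across a set of detected
#' units. Counts sum to the number of units; signature strings are
#' already canonical (edits ordered by consensus position) so equal
#' variants collapse deterministically.
#'
#' @param units data.frame with a `signature` column (from
#'   [find_units()] or simulator truth).
#' @return data.frame `signature`, `count`, sorted by decreasing count
#'   then signature.
#' @export
type_variants <- function(units) {
  stopifnot("signature" %in% names(units))
  tab <- table(units$signature)
  out <- data.frame(
    signature = names(tab), count = as.integer(tab),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$count, out$signature), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Derive satellite arrays and SD-spacer intervals
#'
#' Merges consecutive units separated by at most `max_gap` bp into
#' maximal satellite arrays, then subtracts the arrays from the cap span:
#' the remaining intervals are the SD spacers. Arrays and spacers tile
#' the cap exactly (bp conservation).
#'
#' @param units data.frame of units on one arm (`start`, `end`).
#' @param cap_span Numeric length-2 `c(start, end)` (0-based half-open)
#'   of the subterminal cap region.
#' @param max_gap Maximum within-array gap between consecutive units, bp.
#' @return list with data.frames `arrays` (`start`, `end`, `n_units`)
#'   and `spacers` (`start`, `end`).
#' @export
derive_arrays_and_spacers <- function(units, cap_span, max_gap = 5L) {
  if (length(cap_span) != 2L || cap_span[2] <= cap_span[1]) {
    stop("cap_span must be c(start, end) with end > start")
  }
  if (nrow(units) > 0 &&
      (min(units$start) < cap_span[1] || max(units$end) > cap_span[2])) {
    stop("units outside cap_span")
  }
  if (nrow(units) == 0L) {
    return(list(
      arrays = data.frame(start = integer(), end = integer(), n_units = integer()),
      spacers = data.frame(start = cap_span[1], end = cap_span[2])
    ))
  }
  ir <- bed_to_ir(units$start, units$end)
  merged <- IRanges::reduce(ir, min.gapwidth = max_gap + 1L)
  arrays <- ir_to_bed(merged)
  arrays$n_units <- IRanges::countOverlaps(merged, ir)
  cap_ir <- bed_to_ir(cap_span[1], cap_span[2])
  spacers <- ir_to_bed(IRanges::setdiff(cap_ir, merged))
  list(arrays = arrays, spacers = spacers)
}

#' Annotate every arm of a genome
#'
#' Convenience wrapper running [find_units()], [type_variants()] and
#' [derive_arrays_and_spacers()] across a set of arm sequences. The cap
#' span of each arm is taken as the span of its detected units (or
#' supplied explicitly).
#'
#' @param sequences Named `DNAStringSet` or character vector of arm
#'   sequences.
#' @param consensus A [consensus_model()].
#' @param max_gap Array merging distance, see
#'   [derive_arrays_and_spacers()].
#' @param cap_spans Optional data.frame `arm`, `start`, `end` fixing the
#'   cap span per arm.
#' @return list with `units`, `arrays`, `spacers` (all BED-style
#'   data.frames with an `arm` column) and `variant_counts`.
#' @export
annotate_genome <- function(sequences, consensus = consensus_model(),
                            max_gap = 5L, cap_spans = NULL) {
  arms <- names(sequences)
  stopifnot(!is.null(arms))
  units <- list(); arrays <- list(); spacers <- list()
  for (arm in arms) {
    u <- find_units(as.character(sequences[[arm]]), consensus, arm = arm)
    units[[arm]] <- u
    if (nrow(u) == 0L) next
    span <- if (!is.null(cap_spans)) {
      cs <- cap_spans[cap_spans$arm == arm, ]
      c(cs$start, cs$end)
    } else {
      c(min(u$start), max(u$end))
    }
    der <- derive_arrays_and_spacers(u, span, max_gap = max_gap)
    if (nrow(der$arrays)) arrays[[arm]] <- cbind(arm = arm, der$arrays)
    if (nrow(der$spacers)) spacers[[arm]] <- cbind(arm = arm, der$spacers)
  }
  units <- do.call(rbind, units)
  rownames(units) <- NULL
  list(
    units = units,
    arrays = if (length(arrays)) do.call(rbind, arrays) else NULL,
    spacers = if (length(spacers)) do.call(rbind, spacers) else NULL,
    variant_counts = type_variants(units)
  )
}
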