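# Euchromatin-heterochromatin boundary analyses: boundary windows,
# insertion calling from syntenic alignment gaps, and feature
# enrichment permutation tests.

#' Boundary windows proximal to the caps
#'
#' The euchromatic boundary of a capped arm is the `width` bp
#' immediately proximal to the last cap-proximal satellite unit (for
#' the simulated q-arm-style layout: upstream of the cap start). For
#' capless arms the window is the terminal `width` bp tip.
#'
#' @param caps data.frame `arm`, `start`, `end` of cap spans (rows may
#'   be missing for capless arms).
#' @param arm_lengths Named vector of arm lengths.
#' @param width Window width in bp (2 Mbp on real assemblies; scaled
#'   down for synthetic arms).
#' @return data.frame `arm`, `start`, `end`, `anchor` (the cap edge the
#'   window is measured from).
#' @export
boundary_windows <- function(caps, arm_lengths, width = 2e6) {
  out <- list()
  for (arm in names(arm_lengths)) {
    cap <- caps[caps$arm == arm, ]
    if (nrow(cap) >= 1L) {
      anchor <- cap$start[1]
      start <- max(0L, anchor - width)
      end <- anchor
    } else {
      anchor <- arm_lengths[[arm]]
      start <- max(0L, anchor - width)
      end <- anchor
    }
    out[[arm]] <- data.frame(arm = arm, start = start, end = end,
                             anchor = anchor)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call insertions from syntenic alignment gaps
#'
#' Chains the query arm against its syntenic reference arm with
#' [pairwise_identity()]; query intervals covered by no alignment
#' block and at least `min_size` bp long are emitted as insertions
#' (sequence present in the query but missing from the reference).
#' Each insertion is then re-aligned against a panel of candidate
#' source arms; the best hit covering at least half the insertion
#' assigns its source, otherwise the insertion is `"unplaced"`.
#'
#' @param query_seq,ref_seq The syntenic arm pair (query = the cap
#'   genome arm, ref = the reference homolog).
#' @param sources Optional named sequence set to attribute insertion
#'   origins (e.g. all reference arms).
#' @param min_size Minimum structural event size in bp (default 50).
#' @param min_source_identity Minimum identity for source attribution.
#' @param arm Query arm name for the output.
#' @param ... Passed to [pairwise_identity()].
#' @return data.frame `arm`, `start`, `end`, `length`, `source`.
#' @export
call_insertions <- function(query_seq, ref_seq, sources = NULL,
                            min_size = 50L, min_source_identity = 0.9,
                            arm = "query", ...) {
  q <- toupper(as.character(query_seq))
  blocks <- pairwise_identity(q, as.character(ref_seq), ...)
  qlen <- nchar(q)
  covered <- if (nrow(blocks)) {
    IRanges::reduce(bed_to_ir(blocks$start_a, blocks$end_a))
  } else {
    IRanges::IRanges()
  }
  gaps <- IRanges::setdiff(IRanges::IRanges(1L, qlen), covered)
  gaps <- gaps[IRanges::width(gaps) >= min_size]
  if (length(gaps) == 0L) {
    return(data.frame(arm = character(), start = integer(), end = integer(),
                      length = integer(), source = character()))
  }
  bed <- ir_to_bed(gaps)
  src <- rep("unplaced", nrow(bed))
  if (!is.null(sources)) {
    for (i in seq_len(nrow(bed))) {
      ins <- substr(q, bed$start[i] + 1L, bed$end[i])
      best_id <- 0; best_src <- "unplaced"
      for (nm in names(sources)) {
        bl <- pairwise_identity(ins, as.character(sources[[nm]]),
                                arm_a = "ins", arm_b = nm, ...)
        if (nrow(bl) == 0L) next
        cov <- sum(bl$end_a - bl$start_a)
        id <- sum(bl$matches) / sum(bl$columns)
        if (cov >= 0.5 * nchar(ins) && id >= min_source_identity &&
            id > best_id) {
          best_id <- id; best_src <- nm
        }
      }
      src[i] <- best_src
    }
  }
  data.frame(arm = arm, start = bed$start, end = bed$end,
             length = bed$end - bed$start, source = src)
}

#' Boundary enrichment permutation test
#'
#' Tests whether features (SDs, genes, insertions) are denser inside
#' boundary windows than expected. The statistic is the feature bp
#' density within the windows; the null re-places every feature
#' uniformly (lengths preserved, overlaps allowed) within its
#' chromosome's allowed spans. p is one-sided (null density >= observed),
#' add-one corrected. The fold difference is window density over
#' genome-wide density in the allowed spans.
#'
#' @param features data.frame `arm`, `start`, `end`.
#' @param windows data.frame `arm`, `start`, `end` (boundary windows).
#' @param spans data.frame `arm`, `start`, `end`: the universe for
#'   re-placement (e.g. whole arms minus cap spans).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Seed for the re-placement draws.
#' @return list of class `perm_test`: `observed` (density in windows),
#'   `fold` (vs genome-wide density), `fold_outside` (vs density outside
#'   the windows), `null`, `p`, `n_perm`.
#' @export
boundary_enrichment_test <- function(features, windows, spans,
                                     n_perm = 1000L, seed = 1L) {
  if (nrow(features) == 0L) stop("empty feature set")
  win_bp <- sum(windows$end - windows$start)
  span_bp <- sum(spans$end - spans$start)
  stopifnot(win_bp > 0, span_bp > 0)
  # feature bp inside windows, counted with multiplicity (overlapping
  # features each contribute; a reduce() would saturate under overlap)
  dens <- function(fd) {
    ov <- 0
    for (arm in unique(windows$arm)) {
      w <- windows[windows$arm == arm, , drop = FALSE]
      f <- fd[fd$arm == arm, , drop = FALSE]
      if (nrow(w) == 0L || nrow(f) == 0L) next
      for (r in seq_len(nrow(w))) {
        ov <- ov + sum(pmax(pmin(f$end, w$end[r]) - pmax(f$start, w$start[r]), 0L))
      }
    }
    ov / win_bp
  }
  observed <- dens(features)
  feat_bp <- sum(features$end - features$start)
  genome_density <- feat_bp / span_bp
  fold <- if (genome_density > 0) observed / genome_density else NA_real_
  # fold against the density outside the windows (the generator's own
  # enrichment parameterization; insensitive to window/genome size ratio)
  out_bp <- feat_bp - observed * win_bp
  fold_outside <- if (span_bp > win_bp && out_bp > 0) {
    observed / (out_bp / (span_bp - win_bp))
  } else NA_real_

  # precompute per-arm span pieces for uniform re-placement
  arm_spans <- split(spans, spans$arm)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    fd <- features
    for (i in seq_len(nrow(fd))) {
      w <- fd$end[i] - fd$start[i]
      sp <- arm_spans[[fd$arm[i]]]
      if (is.null(sp)) next
      room <- pmax((sp$end - sp$start) - w, 0L)
      if (all(room == 0L)) next
      piece <- sample.int(nrow(sp), 1L, prob = room)
      fd$start[i] <- sp$start[piece] + sample.int(room[piece], 1L) - 1L
      fd$end[i] <- fd$start[i] + w
    }
    dens(fd)
  }, numeric(1)))
  p <- (1 + sum(null >= observed)) / (1 + n_perm)
  structure(
    list(observed = observed, fold = fold, fold_outside = fold_outside,
         genome_density = genome_density,
         null = null, p = p, n_perm = n_perm,
         direction = "higher density in windows",
         statistic = "feature bp density in boundary windows"),
    class = "perm_test"
  )
}
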