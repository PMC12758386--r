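# Pairwise arm comparison: unique k-mer anchoring, collinear chaining,
# exact identity rescoring. Desk-scale stand-in for whole-genome
# aligners, adequate for the cap regime (long, highly similar segments).

#' Align two arms by unique k-mer anchoring and chaining
#'
#' Finds k-mers that occur exactly once in each sequence, pairs the
#' shared ones into anchors, chains anchors that are collinear on a
#' near-constant diagonal, and reports one alignment block per chain.
#' Identity is recomputed exactly: same-diagonal inter-anchor gaps are
#' compared base-by-base, small shifted gaps are globally re-aligned;
#' a diagonal shift larger than `max_shift` (or a shifted gap longer
#' than `max_align`) starts a new chain. Both orientations are scanned.
#'
#' Tandem satellite interiors contain no unique k-mers, so anchors come
#' from spacers, flanks and variant junctions; `window` (the maximum
#' anchor-to-anchor gap) must exceed the longest anchor desert to chain
#' across whole arrays.
#'
#' @param seq_a,seq_b DNA strings.
#' @param anchor_k Anchor k-mer length (default 21).
#' @param window Maximum gap between consecutive anchors in a chain, bp.
#' @param max_shift Maximum diagonal drift within a chain, bp.
#' @param max_align Maximum shifted-gap length re-aligned exactly rather
#'   than splitting the chain, bp.
#' @param min_anchors Minimum anchors per reported block.
#' @param arm_a,arm_b Identifiers recorded in the output.
#' @return data.frame of blocks: `arm_a`, `start_a`, `end_a`, `arm_b`,
#'   `start_b`, `end_b` (0-based half-open, `b` coordinates always on
#'   the forward strand), `orientation` (`"+"`/`"-"`), `matches`,
#'   `columns`, `identity`.
#' @export
pairwise_identity <- function(seq_a, seq_b, anchor_k = 21L, window = 50000L,
                              max_shift = 100L, max_align = 5000L,
                              min_anchors = 2L, arm_a = "a", arm_b = "b") {
  a <- toupper(as.character(seq_a))
  b <- toupper(as.character(seq_b))
  out <- list()
  for (orient in c("+", "-")) {
    bb <- if (orient == "+") b else reverse_complement(b)
    anchors <- shared_unique_kmers(a, bb, anchor_k)
    if (nrow(anchors) < min_anchors) next
    chains <- chain_anchors(anchors, window, max_shift, max_align)
    for (ch in chains) {
      if (nrow(ch) < min_anchors) next
      blks <- score_and_split(a, bb, ch, anchor_k, max_align)
      for (blk0 in blks) {
        if (blk0$n_anchors < min_anchors) next
        blk <- data.frame(
          arm_a = arm_a, start_a = blk0$start_a, end_a = blk0$end_a,
          arm_b = arm_b, start_b = blk0$start_b, end_b = blk0$end_b,
          orientation = orient,
          matches = blk0$matches, columns = blk0$columns,
          identity = blk0$matches / blk0$columns
        )
        if (orient == "-") {
          nb <- nchar(b)
          sb <- nb - blk$end_b
          eb <- nb - blk$start_b
          blk$start_b <- sb; blk$end_b <- eb
        }
        out[[length(out) + 1L]] <- blk
      }
    }
  }
  if (!length(out)) {
    return(data.frame(
      arm_a = character(), start_a = integer(), end_a = integer(),
      arm_b = character(), start_b = integer(), end_b = integer(),
      orientation = character(), matches = integer(), columns = integer(),
      identity = numeric()
    ))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start_a, res$start_b), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# 0-based start positions of k-mers occurring exactly once in each of
# a and b, for the shared set
shared_unique_kmers <- function(a, b, k) {
  ka <- unique_kmer_positions(a, k)
  kb <- unique_kmer_positions(b, k)
  hit <- match(ka$kmer, kb$kmer)
  sel <- !is.na(hit)
  data.frame(pos_a = ka$pos[sel], pos_b = kb$pos[hit[sel]])
}

unique_kmer_positions <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(data.frame(kmer = character(), pos = integer()))
  starts <- seq_len(n - k + 1L)
  km <- substring(x, starts, starts + k - 1L)
  dup <- duplicated(km) | duplicated(km, fromLast = TRUE)
  data.frame(kmer = km[!dup], pos = starts[!dup] - 1L)
}

# Group anchors into near-constant diagonal bands (split where the
# sorted diagonals jump by more than max_shift), then chain each band
# left to right with monotone coordinates and bounded gaps. Returns a
# list of data.frames (pos_a, pos_b), each a chain.
chain_anchors <- function(anchors, window, max_shift, max_align) {
  d <- anchors$pos_a - anchors$pos_b
  ord <- order(d, anchors$pos_a)
  pa <- anchors$pos_a[ord]; pb <- anchors$pos_b[ord]; dd <- d[ord]
  band <- cumsum(c(1L, diff(dd) > max_shift))
  chains <- list()
  for (ids in split(seq_along(pa), band)) {
    ids <- ids[order(pa[ids])]
    xa <- pa[ids]; xb <- pb[ids]
    n <- length(ids)
    chain_id <- integer(n)
    chain_id[1] <- 1L
    last_a <- xa[1]; last_b <- xb[1]; cur <- 1L
    keep <- rep(TRUE, n)
    if (n > 1L) for (i in 2:n) {
      ga <- xa[i] - last_a; gb <- xb[i] - last_b
      if (ga <= 0L || gb <= 0L) {
        # crossing/stray anchor inside a tight band: drop it
        keep[i] <- FALSE
        next
      }
      shift <- abs(ga - gb)
      if (ga <= window && gb <= window &&
          (shift == 0L || max(ga, gb) <= max_align)) {
        chain_id[i] <- cur
      } else {
        cur <- cur + 1L
        chain_id[i] <- cur
      }
      last_a <- xa[i]; last_b <- xb[i]
    }
    for (cid in split(which(keep), chain_id[keep])) {
      chains[[length(chains) + 1L]] <- data.frame(pos_a = xa[cid], pos_b = xb[cid])
    }
  }
  chains
}

# Walk a chain computing exact matches/columns, and split it into
# blocks at weak long gaps (identity below split_identity over at least
# split_min_len bp), so that a high-identity segment is not diluted by
# an adjacent merely-homologous one. Anchors match by construction;
# same-diagonal gaps are compared bytewise; shifted gaps re-aligned.
score_and_split <- function(a, b, ch, k, max_align,
                            split_identity = 0.99, split_min_len = 100L) {
  n <- nrow(ch)
  blocks <- list()
  bl_start <- 1L
  matches <- k; columns <- k; n_anchors <- 1L
  submat <- NULL
  close_block <- function(i_end) {
    blocks[[length(blocks) + 1L]] <<- list(
      start_a = ch$pos_a[bl_start], end_a = ch$pos_a[i_end] + k,
      start_b = ch$pos_b[bl_start], end_b = ch$pos_b[i_end] + k,
      matches = matches, columns = columns, n_anchors = n_anchors
    )
  }
  if (n > 1L) for (i in 2:n) {
    a0 <- ch$pos_a[i - 1L] + k; a1 <- ch$pos_a[i]
    b0 <- ch$pos_b[i - 1L] + k; b1 <- ch$pos_b[i]
    gm <- 0L; gc <- 0L # gap matches / columns
    if (a1 - a0 == b1 - b0) {
      if (a1 > a0) {
        ga <- charToRaw(substr(a, a0 + 1L, a1))
        gb <- charToRaw(substr(b, b0 + 1L, b1))
        gm <- sum(ga == gb); gc <- length(ga)
      }
      adv <- min(k, a1 - ch$pos_a[i - 1L]) # anchor may overlap previous
      gm <- gm + adv; gc <- gc + adv
    } else if (a1 <= a0 || b1 <= b0) {
      # overlapping anchors across a small shift: count conservatively
      adv <- max(a1 - a0, b1 - b0, 0L) + k
      shift <- abs((a1 - a0) - (b1 - b0))
      gm <- max(adv - shift, 0L); gc <- adv
    } else {
      ga <- substr(a, a0 + 1L, a1)
      gb <- substr(b, b0 + 1L, b1)
      if (is.null(submat)) {
        submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
      }
      pa <- Biostrings::pairwiseAlignment(
        pattern = Biostrings::DNAString(ga), subject = Biostrings::DNAString(gb),
        type = "global", substitutionMatrix = submat,
        gapOpening = 4, gapExtension = 1
      )
      s1 <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
      s2 <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
      gm <- sum(s1 == s2 & s1 != "-") + k
      gc <- length(s1) + k
    }
    gap_len <- max(a1 - a0, b1 - b0, 0L)
    if (gap_len >= split_min_len && gm / gc < split_identity) {
      close_block(i - 1L)
      bl_start <- i
      matches <- k; columns <- k; n_anchors <- 1L
    } else {
      matches <- matches + gm; columns <- columns + gc
      n_anchors <- n_anchors + 1L
    }
  }
  close_block(n)
  blocks
}

#' Detect ectopic-exchange candidates from alignment blocks
#'
#' Filters nonallelic alignment blocks to those above the identity and
#' span thresholds (the recent-exchange regime), merges them per arm
#' pair, and reports the proximal (centromere-side) edge of the merged
#' high-identity region on each arm as the refined breakpoint — an
#' exchanged distal segment runs from the breakpoint to the telomere.
#'
#' @param blocks data.frame from [pairwise_identity()] runs, with
#'   `arm_a`/`arm_b` naming nonallelic arm pairs.
#' @param min_identity Minimum block identity (default 0.995).
#' @param min_span Minimum block span in bp on arm a (scaled-down
#'   stand-in for the megabase filter used on real assemblies).
#' @return data.frame of candidates: `arm_a`, `arm_b`, `breakpoint_a`,
#'   `breakpoint_b`, `span`, `identity`, `identity_class`
#'   (`">99.8%"` or `">99.5%"`), sorted by decreasing span.
#' @export
detect_candidates <- function(blocks, min_identity = 0.995, min_span = 20000L) {
  sel <- blocks$identity > min_identity &
    (blocks$end_a - blocks$start_a) >= min_span
  hi <- blocks[sel, , drop = FALSE]
  if (nrow(hi) == 0L) {
    return(data.frame(
      arm_a = character(), arm_b = character(),
      breakpoint_a = integer(), breakpoint_b = integer(),
      span = integer(), identity = numeric(), identity_class = character()
    ))
  }
  key <- paste(hi$arm_a, hi$arm_b, sep = "\r")
  out <- lapply(split(hi, key), function(g) {
    span_a <- sum(g$end_a - g$start_a)
    data.frame(
      arm_a = g$arm_a[1], arm_b = g$arm_b[1],
      breakpoint_a = min(g$start_a), breakpoint_b = min(g$start_b),
      span = span_a,
      identity = sum(g$matches) / sum(g$columns)
    )
  })
  out <- do.call(rbind, out)
  out$identity_class <- ifelse(out$identity > 0.998, ">99.8%", ">99.5%")
  out <- out[order(-out$span), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Allelic vs nonallelic identity profile
#'
#' Computes per-window sequence identity for every allelic haplotype
#' pair (50 kbp nonoverlapping windows on real assemblies; scaled for
#' synthetic arms) and contrasts mean allelic identity against
#' nonallelic arm pairs with a two-sided label-permutation test.
#'
#' @param hap1,hap2 Named sequence sets (`DNAStringSet` or character).
#' @param allelic_map data.frame `arm1`, `arm2` pairing allelic arms
#'   across haplotypes; all other cross pairs are nonallelic.
#' @param window Window width in bp.
#' @param n_perm Label permutations (default 1000).
#' @param seed Seed for the permutation draw.
#' @param ... Passed to [pairwise_identity()].
#' @return list: `windows` (data.frame `arm1`, `arm2`, `start`, `end`,
#'   `identity`, NA where unaligned), `pair_identity` (per-pair mean),
#'   `test` (observed mean difference allelic - nonallelic, permutation
#'   p, n_perm).
#' @export
allelic_identity_profile <- function(hap1, hap2, allelic_map, window = 50000L,
                                     n_perm = 1000L, seed = 1L, ...) {
  stopifnot(all(c("arm1", "arm2") %in% names(allelic_map)))
  pairs <- expand.grid(arm1 = names(hap1), arm2 = names(hap2),
                       stringsAsFactors = FALSE)
  key <- function(x, y) paste(x, y, sep = "\r")
  pairs$allelic <- key(pairs$arm1, pairs$arm2) %in%
    key(allelic_map$arm1, allelic_map$arm2)
  win_rows <- list()
  pair_rows <- list()
  for (i in seq_len(nrow(pairs))) {
    a1 <- pairs$arm1[i]; a2 <- pairs$arm2[i]
    sa <- as.character(hap1[[a1]]); sb <- as.character(hap2[[a2]])
    if (window > nchar(sa)) stop("window larger than arm ", a1)
    blocks <- pairwise_identity(sa, sb, arm_a = a1, arm_b = a2, ...)
    wi <- window_identity(blocks, nchar(sa), window)
    wi <- cbind(arm1 = a1, arm2 = a2, wi, allelic = pairs$allelic[i])
    win_rows[[i]] <- wi
    pair_rows[[i]] <- data.frame(
      arm1 = a1, arm2 = a2, allelic = pairs$allelic[i],
      identity = if (all(is.na(wi$identity))) NA_real_ else
        mean(wi$identity, na.rm = TRUE)
    )
  }
  windows <- do.call(rbind, win_rows)
  pair_id <- do.call(rbind, pair_rows)
  rownames(windows) <- rownames(pair_id) <- NULL

  ok <- !is.na(pair_id$identity)
  x <- pair_id$identity[ok]
  lab <- pair_id$allelic[ok]
  if (!any(lab) || all(lab)) {
    test <- list(observed = NA_real_, p = NA_real_, n_perm = n_perm)
  } else {
    obs <- mean(x[lab]) - mean(x[!lab])
    null <- with_seed(seed, vapply(seq_len(n_perm), function(j) {
      l <- sample(lab)
      mean(x[l]) - mean(x[!l])
    }, numeric(1)))
    p <- (1 + sum(abs(null) >= abs(obs))) / (1 + n_perm)
    test <- list(observed = obs, p = p, n_perm = n_perm)
  }
  list(windows = windows, pair_identity = pair_id, test = test)
}

# per-window identity on arm-a coordinates from alignment blocks:
# coverage-weighted mean of block identity; NA for uncovered windows
window_identity <- function(blocks, len_a, window) {
  starts <- seq(0L, len_a - 1L, by = window)
  ends <- pmin(starts + window, len_a)
  ident <- rep(NA_real_, length(starts))
  for (w in seq_along(starts)) {
    if (nrow(blocks) == 0L) break
    ov <- pmin(blocks$end_a, ends[w]) - pmax(blocks$start_a, starts[w])
    sel <- ov > 0
    if (any(sel)) {
      ident[w] <- sum(blocks$identity[sel] * ov[sel]) / sum(ov[sel])
    }
  }
  data.frame(start = starts, end = ends, identity = ident)
}
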