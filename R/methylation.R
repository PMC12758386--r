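# CpG methylation: strand merging, coverage filtering, and profiling
# across compartments and the heterochromatin-euchromatin boundary.

#' Merge strand-specific CpG calls into per-CpG sites
#'
#' CpG methylation is symmetric, so the modified/total counts of the
#' two cytosines of a CpG dinucleotide are summed into one site keyed
#' by the position of the + strand C. Sites with fewer than
#' `min_coverage` merged reads are dropped (after the merge). Counts
#' are conserved before the coverage filter; calls at non-CpG
#' positions (checked when `sequences` is supplied) are skipped with a
#' warning and counted.
#'
#' Already-merged input (strand `"."` or `"+"`-only rows at CpG
#' positions) passes through unchanged apart from the filter, so the
#' operation is idempotent.
#'
#' @param calls data.frame `chrom`, `start`, `end`, `strand` (`"+"`,
#'   `"-"` or `"."`), `n_mod`, `n_total` (bedMethyl-like, 0-based).
#' @param sequences Optional named sequence set for CpG validation.
#' @param min_coverage Minimum merged read total (default 5).
#' @return data.frame `chrom`, `start`, `end` (the CpG dinucleotide),
#'   `n_mod`, `n_total`, `fraction`, sorted by position. Attributes:
#'   `n_skipped` (non-CpG calls), `unfiltered` (pre-filter totals:
#'   `n_sites`, `n_mod`, `n_total`).
#' @export
merge_cpg <- function(calls, sequences = NULL, min_coverage = 5L) {
  need <- c("chrom", "start", "strand", "n_mod", "n_total")
  stopifnot(all(need %in% names(calls)))
  if (any(calls$n_mod > calls$n_total)) stop("n_mod exceeds n_total")
  # CpG anchor = position of the + strand C
  cpg <- ifelse(calls$strand == "-", calls$start - 1L, calls$start)
  skipped <- rep(FALSE, nrow(calls))
  if (!is.null(sequences)) {
    for (chrom in unique(calls$chrom)) {
      sel <- which(calls$chrom == chrom)
      s <- toupper(as.character(sequences[[chrom]]))
      di <- substring(s, cpg[sel] + 1L, cpg[sel] + 2L)
      skipped[sel] <- di != "CG"
    }
    if (any(skipped)) {
      warning(sum(skipped), " call(s) at non-CpG positions skipped")
    }
  }
  ok <- !skipped
  key <- paste(calls$chrom[ok], cpg[ok], sep = "\r")
  agg_mod <- rowsum(calls$n_mod[ok], key)
  agg_tot <- rowsum(calls$n_total[ok], key)
  parts <- do.call(rbind, strsplit(rownames(agg_mod), "\r", fixed = TRUE))
  out <- data.frame(
    chrom = parts[, 1],
    start = as.integer(parts[, 2]),
    end = as.integer(parts[, 2]) + 2L,
    n_mod = as.integer(agg_mod[, 1]),
    n_total = as.integer(agg_tot[, 1])
  )
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  unfiltered <- list(n_sites = nrow(out), n_mod = sum(out$n_mod),
                     n_total = sum(out$n_total))
  out <- out[out$n_total >= min_coverage, , drop = FALSE]
  out$fraction <- ifelse(out$n_total > 0, out$n_mod / out$n_total, NA_real_)
  rownames(out) <- NULL
  attr(out, "n_skipped") <- sum(skipped)
  attr(out, "unfiltered") <- unfiltered
  out
}

#' Methylation profile across features and boundary windows
#'
#' Summarizes merged CpG sites per feature class (mean, SD, site
#' count), runs two-sided Wilcoxon rank-sum comparisons between every
#' pair of classes, reports the Spearman correlation between interval
#' length and mean methylation for the first feature class (the
#' spacer-length relationship), and, when boundary windows are given,
#' bins sites by distance to the cap edge.
#'
#' @param sites Output of [merge_cpg()] (needs `chrom`, `start`,
#'   `fraction`).
#' @param features Named list of BED-style data.frames (`arm`, `start`,
#'   `end`), one per class (e.g. `satellite`, `spacer`, `flank`).
#' @param boundaries Optional data.frame `arm`, `start`, `end`,
#'   `anchor` where `anchor` is the cap-proximal edge position; bins
#'   measure distance from the anchor into the euchromatin.
#' @param bin_width Profile bin width in bp (default 1000).
#' @return list: `class_means` (data.frame `class`, `mean`, `sd`,
#'   `n_sites`), `tests` (pairwise rank-sum p-values), `per_interval`
#'   (per feature interval mean fraction and length),
#'   `length_correlation` (Spearman rho and p for the first class),
#'   `profile` (per-bin mean and SD, or NULL).
#' @export
methylation_profile <- function(sites, features, boundaries = NULL,
                                bin_width = 1000L) {
  stopifnot(is.list(features), !is.null(names(features)))
  cls_of_site <- function(fd) {
    hit <- rep(FALSE, nrow(sites))
    for (arm in unique(fd$arm)) {
      iv <- fd[fd$arm == arm, , drop = FALSE]
      sel <- sites$chrom == arm
      if (!any(sel) || nrow(iv) == 0L) next
      ir <- bed_to_ir(iv$start, iv$end)
      hit[sel] <- IRanges::overlapsAny(
        IRanges::IRanges(sites$start[sel] + 1L, sites$start[sel] + 1L), ir
      )
    }
    hit
  }
  member <- lapply(features, cls_of_site)
  class_means <- do.call(rbind, lapply(names(features), function(nm) {
    fr <- sites$fraction[member[[nm]]]
    data.frame(class = nm, mean = mean(fr), sd = stats::sd(fr),
               n_sites = length(fr))
  }))
  # pairwise two-sided rank-sum tests
  tests <- list()
  nms <- names(features)
  if (length(nms) >= 2L) {
    for (i in seq_len(length(nms) - 1L)) {
      for (j in (i + 1L):length(nms)) {
        xi <- sites$fraction[member[[nms[i]]]]
        xj <- sites$fraction[member[[nms[j]]]]
        p <- if (length(xi) && length(xj)) {
          if (length(unique(c(xi, xj))) == 1L) 1 else
            stats::wilcox.test(xi, xj, exact = FALSE)$p.value
        } else NA_real_
        tests[[paste(nms[i], nms[j], sep = " vs ")]] <- p
      }
    }
  }
  # per-interval means for the first class (spacers in the cap use)
  fd1 <- features[[1]]
  per_interval <- do.call(rbind, lapply(seq_len(nrow(fd1)), function(r) {
    sel <- sites$chrom == fd1$arm[r] &
      sites$start >= fd1$start[r] & sites$start < fd1$end[r]
    data.frame(
      arm = fd1$arm[r], start = fd1$start[r], end = fd1$end[r],
      length = fd1$end[r] - fd1$start[r],
      mean_fraction = if (any(sel)) mean(sites$fraction[sel]) else NA_real_,
      n_sites = sum(sel)
    )
  }))
  lc <- list(rho = NA_real_, p = NA_real_)
  ok <- !is.na(per_interval$mean_fraction)
  if (sum(ok) >= 3L && stats::sd(per_interval$length[ok]) > 0 &&
      stats::sd(per_interval$mean_fraction[ok]) > 0) {
    ct <- stats::cor.test(per_interval$length[ok],
                          per_interval$mean_fraction[ok],
                          method = "spearman", exact = FALSE)
    lc <- list(rho = unname(ct$estimate), p = ct$p.value)
  }
  profile <- NULL
  if (!is.null(boundaries)) {
    rows <- list()
    for (r in seq_len(nrow(boundaries))) {
      sel <- sites$chrom == boundaries$arm[r] &
        sites$start >= boundaries$start[r] & sites$start < boundaries$end[r]
      if (!any(sel)) next
      dist <- abs(boundaries$anchor[r] - sites$start[sel])
      rows[[r]] <- data.frame(bin = floor(dist / bin_width),
                              fraction = sites$fraction[sel])
    }
    if (length(rows)) {
      dd <- do.call(rbind, rows)
      agg_m <- tapply(dd$fraction, dd$bin, mean)
      agg_s <- tapply(dd$fraction, dd$bin, stats::sd)
      agg_n <- tapply(dd$fraction, dd$bin, length)
      profile <- data.frame(
        dist_lo = as.integer(names(agg_m)) * bin_width,
        dist_hi = (as.integer(names(agg_m)) + 1L) * bin_width,
        mean = as.numeric(agg_m), sd = as.numeric(agg_s),
        n_sites = as.integer(agg_n)
      )
    }
  }
  list(class_means = class_means, tests = tests,
       per_interval = per_interval, length_correlation = lc,
       profile = profile)
}
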