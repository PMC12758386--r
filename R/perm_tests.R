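# Statistical tests for ectopic recombination: breakpoint-to-spacer
# proximity by permutation, and the half-alignment Robinson-Foulds
# shift test.

#' Breakpoint-to-spacer proximity permutation test
#'
#' Tests whether ectopic-exchange breakpoints lie closer to SD spacers
#' than expected by chance. The statistic is the mean distance from
#' each breakpoint to the nearest spacer base (zero if inside one);
#' the null re-places each breakpoint uniformly within its own cap
#' span, `n_perm` times. "More extreme" means a null mean distance as
#' small as or smaller than observed (the proximity direction), with
#' the add-one correction so p is never zero. A one-sided Wilcoxon
#' rank-sum comparison of the observed per-breakpoint distances versus
#' the pooled null distances is reported alongside.
#'
#' @param breakpoints data.frame `arm`, `pos`.
#' @param spacers data.frame `arm`, `start`, `end`.
#' @param caps data.frame `arm`, `start`, `end` cap spans.
#' @param n_perm Number of shuffles (default 1000).
#' @param seed Seed for the shuffles.
#' @return list of class `perm_test`: `observed`, `null` (numeric
#'   vector), `p` (= (1 + #\{null <= observed\}) / (1 + n_perm)),
#'   `p_wilcoxon`, `direction` = "smaller mean distance", `n_perm`.
#' @export
breakpoint_spacer_test <- function(breakpoints, spacers, caps,
                                   n_perm = 1000L, seed = 1L) {
  stopifnot(nrow(breakpoints) >= 1L)
  if (nrow(spacers) == 0L) stop("empty spacer set")
  arms <- unique(breakpoints$arm)
  missing_caps <- setdiff(arms, caps$arm)
  if (length(missing_caps)) {
    stop("no cap span for arm(s): ", paste(missing_caps, collapse = ", "))
  }
  obs_d <- spacer_distances(breakpoints, spacers)
  observed <- mean(obs_d)
  null_mat <- with_seed(seed, {
    draws <- matrix(NA_real_, n_perm, nrow(breakpoints))
    for (j in seq_len(nrow(breakpoints))) {
      cap <- caps[caps$arm == breakpoints$arm[j], ][1, ]
      pos <- cap$start + sample.int(cap$end - cap$start, n_perm, replace = TRUE) - 1L
      draws[, j] <- spacer_distances(
        data.frame(arm = breakpoints$arm[j], pos = pos), spacers
      )
    }
    draws
  })
  null <- rowMeans(null_mat)
  p <- (1 + sum(null <= observed)) / (1 + n_perm)
  pw <- tryCatch(
    stats::wilcox.test(obs_d, as.numeric(null_mat),
                       alternative = "less", exact = FALSE)$p.value,
    error = function(e) NA_real_
  )
  structure(
    list(observed = observed, null = null, p = p, p_wilcoxon = pw,
         direction = "smaller mean distance", n_perm = n_perm,
         statistic = "mean bp distance to nearest spacer"),
    class = "perm_test"
  )
}

# distance from each breakpoint to the nearest spacer base on its arm
# (0 inside a spacer); Inf when the arm has no spacer
spacer_distances <- function(breakpoints, spacers) {
  out <- numeric(nrow(breakpoints))
  for (arm in unique(breakpoints$arm)) {
    sel <- breakpoints$arm == arm
    sp <- spacers[spacers$arm == arm, , drop = FALSE]
    if (nrow(sp) == 0L) { out[sel] <- Inf; next }
    pos <- breakpoints$pos[sel]
    d <- vapply(pos, function(p) {
      # per interval: 0 if inside, else gap to the nearer edge
      min(pmax(pmax(sp$start - p, p - sp$end + 1L), 0L))
    }, numeric(1))
    out[sel] <- d
  }
  out
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf(
    "permutation test (%s)\n  observed = %.4g, null mean = %.4g, p = %.4g (n_perm = %d)\n",
    x$statistic %||% "statistic", x$observed, mean(x$null), x$p, x$n_perm
  ))
  invisible(x)
}

#' Robinson-Foulds distance between two trees
#'
#' Unrooted symmetric bipartition distance (the count of bipartitions
#' present in exactly one of the trees).
#'
#' @param t1,t2 `phylo` objects on the same tips.
#' @return Non-negative integer.
#' @export
rf_distance <- function(t1, t2) {
  # RF.dist chats via message() when a tree is multifurcating (the
  # majority-rule consensus routinely is); the distance is still the
  # symmetric bipartition count we want
  suppressMessages(suppressWarnings(
    phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2), check.labels = TRUE)
  ))
}

#' Half-alignment Robinson-Foulds shift test for recombination
#'
#' If SD spacers recombine internally, the phylogeny of the first half
#' of the spacer alignment should differ from that of the second half
#' and from the full-alignment tree. The observed statistics are
#' RF(full tree, half-i tree) for the two halves (first ceiling(L/2)
#' columns / remainder). The null distribution is built from `n_boot`
#' site-resampled bootstrap trees of the full alignment: the RF
#' distance of each bootstrap tree to their majority-rule consensus.
#' p_i = (1 + #\{null >= observed_i\}) / (1 + n_boot).
#'
#' @param aln Equal-width alignment (>= 4 taxa).
#' @param n_boot Bootstrap replicates for the null (default 1000).
#' @param model Distance model for [nj_tree()].
#' @param seed Seed for the resampling.
#' @return list of class `rf_shift`: `rf_first`, `rf_second`,
#'   `p_first`, `p_second`, `null` (numeric vector), `trees`
#'   (full/first/second/consensus), `n_boot`.
#' @export
rf_shift_test <- function(aln, n_boot = 1000L, model = "JC69", seed = 1L) {
  m <- as_aln_matrix(aln)
  if (nrow(m) < 4L) stop("need at least 4 taxa")
  L <- ncol(m)
  half <- ceiling(L / 2)
  t_full <- nj_tree(m, model = model, n_boot = 0L)
  t1 <- nj_tree(m[, seq_len(half), drop = FALSE], model = model, n_boot = 0L)
  t2 <- nj_tree(m[, (half + 1L):L, drop = FALSE], model = model, n_boot = 0L)
  rf1 <- rf_distance(t_full, t1)
  rf2 <- rf_distance(t_full, t2)
  boot_trees <- with_seed(seed, lapply(seq_len(n_boot), function(b) {
    cols <- sample.int(L, replace = TRUE)
    clamp_negative_edges(ape::nj(jc69_dist(m[, cols, drop = FALSE], model)))
  }))
  class(boot_trees) <- "multiPhylo"
  cons <- ape::consensus(boot_trees, p = 0.5)
  null <- vapply(boot_trees, function(bt) rf_distance(cons, bt), numeric(1))
  p1 <- (1 + sum(null >= rf1)) / (1 + n_boot)
  p2 <- (1 + sum(null >= rf2)) / (1 + n_boot)
  structure(
    list(rf_first = rf1, rf_second = rf2, p_first = p1, p_second = p2,
         null = null,
         trees = list(full = t_full, first = t1, second = t2, consensus = cons),
         n_boot = n_boot),
    class = "rf_shift"
  )
}

#' @export
print.rf_shift <- function(x, ...) {
  cat(sprintf(
    "RF shift test: RF(full, first) = %d (p = %.4g), RF(full, second) = %d (p = %.4g)\n",
    x$rf_first, x$p_first, x$rf_second, x$p_second
  ))
  invisible(x)
}
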