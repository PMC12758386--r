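# Distance phylogeny of SD spacers: JC69 + neighbor-joining with
# site-resampled bootstrap support, and strict-clock node dating against
# fixed ape divergence times.

#' Ape divergence calibration ages
#'
#' The divergence times (MYA) of human versus chimpanzee, gorilla,
#' orangutan and siamang used to timescale spacer phylogenies.
#'
#' @return data.frame with columns `lineage` and `age_mya`
#'   (6.4, 8.6, 15.2, 19.5).
#' @export
divergence_calibrations <- function() {
  data.frame(
    lineage = c("chimpanzee", "gorilla", "orangutan", "siamang"),
    age_mya = c(6.4, 8.6, 15.2, 19.5)
  )
}

# JC69-corrected distance matrix from an equal-width alignment;
# errors on saturated pairs (p >= 0.75), naming the pair.
jc69_dist <- function(aln, model = c("JC69", "raw")) {
  model <- match.arg(model)
  m <- as_aln_matrix(aln)
  n <- nrow(m)
  labs <- rownames(m)
  p <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      cmp <- m[i, ] != m[j, ]
      pd <- mean(cmp)
      if (model == "JC69") {
        if (pd >= 0.75) {
          stop("JC69 distance saturated (p = ", signif(pd, 3), ") for pair ",
               labs[i], " / ", labs[j])
        }
        pd <- -0.75 * log(1 - 4 * pd / 3)
      }
      p[i, j] <- p[j, i] <- pd
    }
  }
  stats::as.dist(p)
}

as_aln_matrix <- function(aln) {
  if (is.matrix(aln)) return(aln)
  nm <- names(aln) # as.character() drops names, so take them first
  chr <- as.character(aln)
  if (length(unique(nchar(chr))) != 1L) stop("alignment rows differ in width")
  m <- do.call(rbind, strsplit(chr, ""))
  rownames(m) <- if (is.null(nm)) sprintf("seq%03d", seq_along(chr)) else nm
  m
}

#' Neighbor-joining tree with bootstrap support
#'
#' Builds a neighbor-joining tree from JC69-corrected (or raw) pairwise
#' p-distances, with support values from site-resampled bootstrap
#' replicates. Negative NJ branch lengths are clamped to zero with the
#' deficit transferred to the sibling branch, preserving path lengths
#' through the parent node.
#'
#' @param aln Equal-width alignment (`DNAStringSet`, named character
#'   vector, or character matrix).
#' @param model `"JC69"` (default) or `"raw"` p-distance.
#' @param n_boot Bootstrap replicates (default 1000; 0 skips support).
#' @param seed Seed for the resampling.
#' @return `phylo` with `node.label` bootstrap percentages and
#'   attribute `boot_trees` (a `multiPhylo` of the replicates).
#' @export
nj_tree <- function(aln, model = "JC69", n_boot = 1000L, seed = 1L) {
  m <- as_aln_matrix(aln)
  if (nrow(m) < 3L) stop("need at least 3 sequences")
  tree <- clamp_negative_edges(ape::nj(jc69_dist(m, model)))
  if (n_boot > 0L) {
    boot_trees <- with_seed(seed, lapply(seq_len(n_boot), function(b) {
      cols <- sample.int(ncol(m), replace = TRUE)
      clamp_negative_edges(ape::nj(jc69_dist(m[, cols, drop = FALSE], model)))
    }))
    class(boot_trees) <- "multiPhylo"
    counts <- ape::prop.clades(tree, boot_trees, rooted = FALSE)
    counts[is.na(counts)] <- 0L
    tree$node.label <- formatC(100 * counts / n_boot, format = "d")
    attr(tree, "boot_trees") <- boot_trees
  }
  tree
}

# zero out negative branch lengths, adding the deficit to the sibling
# edge (the standard NJ cleanup; keeps parent-path lengths)
clamp_negative_edges <- function(tree) {
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    child <- tree$edge[e, 2]
    parent <- tree$edge[e, 1]
    sib <- which(tree$edge[, 1] == parent & tree$edge[, 2] != child)
    if (length(sib)) {
      tree$edge.length[sib[1]] <- tree$edge.length[sib[1]] + tree$edge.length[e]
    }
    tree$edge.length[e] <- 0
  }
  tree
}

#' Strict-clock time calibration of a spacer tree
#'
#' Roots the tree on the outgroup of the oldest calibration, measures
#' every internal node's height (mean substitutions/site down to its
#' descendant tips), fits one global substitution rate by least squares
#' through the calibrated nodes (`rate = sum(h * a) / sum(a^2)` over
#' calibration heights `h` and ages `a`), and converts heights to ages.
#' Confidence intervals come from re-dating site-resampled bootstrap
#' trees and collecting, per bipartition of the main tree, the 2.5 and
#' 97.5 percentiles.
#'
#' @param tree Rooted or unrooted `phylo` from [nj_tree()].
#' @param calibrations data.frame with columns `tip_a`, `tip_b`,
#'   `age_mya`: each row pins the MRCA of the two tips to an age. The
#'   oldest row's `tip_b` is taken as the outgroup for rooting.
#' @param aln Optional alignment for bootstrap confidence intervals.
#' @param n_boot_ci Bootstrap replicates for the CI (default 100).
#' @param model,seed Passed to the bootstrap [nj_tree()] runs.
#' @return list of class `calibrated_tree`: `tree` (rooted phylo),
#'   `rate` (subs/site/MY), `ages` (data.frame `node`, `height`,
#'   `age_mya`, `ci_lo`, `ci_hi`), `calibrations`.
#' @export
calibrate <- function(tree, calibrations, aln = NULL, n_boot_ci = 100L,
                      model = "JC69", seed = 1L) {
  stopifnot(all(c("tip_a", "tip_b", "age_mya") %in% names(calibrations)))
  missing <- setdiff(unique(c(calibrations$tip_a, calibrations$tip_b)),
                     tree$tip.label)
  if (length(missing)) {
    stop("calibration tips absent from tree: ", paste(missing, collapse = ", "))
  }
  root_tip <- calibrations$tip_b[which.max(calibrations$age_mya)]
  fit <- calibrate_one(tree, calibrations, root_tip)

  ages <- fit$ages
  ages$ci_lo <- NA_real_; ages$ci_hi <- NA_real_
  if (!is.null(aln)) {
    m <- as_aln_matrix(aln)
    boot_ages <- with_seed(seed, lapply(seq_len(n_boot_ci), function(b) {
      cols <- sample.int(ncol(m), replace = TRUE)
      bt <- try(clamp_negative_edges(ape::nj(jc69_dist(m[, cols, drop = FALSE], model))),
                silent = TRUE)
      if (inherits(bt, "try-error")) return(NULL)
      bf <- try(calibrate_one(bt, calibrations, root_tip), silent = TRUE)
      if (inherits(bf, "try-error")) return(NULL)
      bf
    }))
    # match nodes across replicates by their descendant tip sets
    key_of <- function(tr, nodes) {
      vapply(nodes, function(nd) {
        tips <- ape::extract.clade(tr, nd)$tip.label
        paste(sort(tips), collapse = "|")
      }, character(1))
    }
    main_keys <- key_of(fit$tree, ages$node)
    acc <- stats::setNames(vector("list", length(main_keys)), main_keys)
    for (bf in boot_ages) {
      if (is.null(bf)) next
      bk <- key_of(bf$tree, bf$ages$node)
      hit <- match(bk, main_keys)
      for (i in which(!is.na(hit))) {
        k <- main_keys[hit[i]]
        acc[[k]] <- c(acc[[k]], bf$ages$age_mya[i])
      }
    }
    for (i in seq_along(main_keys)) {
      v <- acc[[main_keys[i]]]
      if (length(v) >= 2L) {
        q <- stats::quantile(v, c(0.025, 0.975), names = FALSE)
        ages$ci_lo[i] <- q[1]; ages$ci_hi[i] <- q[2]
      }
    }
  }
  structure(
    list(tree = fit$tree, rate = fit$rate, ages = ages,
         calibrations = calibrations),
    class = "calibrated_tree"
  )
}

# root, measure node heights, fit the clock rate, date all nodes
calibrate_one <- function(tree, calibrations, root_tip) {
  rooted <- ape::root(tree, outgroup = root_tip, resolve.root = TRUE)
  rooted <- balance_root_edge(rooted, root_tip)
  n_tip <- length(rooted$tip.label)
  depths <- ape::node.depth.edgelength(rooted) # root -> node path length
  # node height = mean path length to descendant tips
  heights <- numeric(n_tip + rooted$Nnode)
  tip_sets <- vector("list", n_tip + rooted$Nnode)
  for (i in seq_len(n_tip)) tip_sets[[i]] <- i
  po <- ape::postorder(rooted)
  for (e in po) {
    par <- rooted$edge[e, 1]; child <- rooted$edge[e, 2]
    tip_sets[[par]] <- c(tip_sets[[par]], tip_sets[[child]])
  }
  internal <- n_tip + seq_len(rooted$Nnode)
  for (nd in internal) {
    tips <- tip_sets[[nd]]
    heights[nd] <- mean(depths[tips]) - depths[nd]
  }
  # monotone cleanup: a parent is at least as high as its children
  for (e in po) {
    par <- rooted$edge[e, 1]; child <- rooted$edge[e, 2]
    if (child > n_tip) heights[par] <- max(heights[par], heights[child])
  }
  cal_nodes <- mapply(function(a, b) ape::getMRCA(rooted, c(a, b)),
                      calibrations$tip_a, calibrations$tip_b)
  h <- heights[cal_nodes]; a <- calibrations$age_mya
  rate <- sum(h * a) / sum(a * a)
  if (!is.finite(rate) || rate <= 0) stop("calibration rate fit failed")
  ages <- data.frame(
    node = internal,
    height = heights[internal],
    age_mya = heights[internal] / rate
  )
  list(tree = rooted, rate = rate, ages = ages)
}

# ape::root() leaves the root at the outgroup's attachment node (the
# outgroup edge is not split), which biases the root height low under a
# clock. Slide the root along the outgroup edge so that the outgroup
# depth equals the mean ingroup tip depth.
balance_root_edge <- function(rooted, root_tip) {
  n_tip <- length(rooted$tip.label)
  root <- n_tip + 1L
  kids <- which(rooted$edge[, 1] == root)
  if (length(kids) != 2L) return(rooted)
  out_idx <- match(root_tip, rooted$tip.label)
  is_out <- vapply(kids, function(e) {
    child <- rooted$edge[e, 2]
    if (child <= n_tip) child == out_idx else
      out_idx %in% unlist(phangorn::Descendants(rooted, child, "tips"))
  }, logical(1))
  if (sum(is_out) != 1L) return(rooted)
  e_out <- kids[is_out]; e_in <- kids[!is_out]
  D <- rooted$edge.length[e_out] + rooted$edge.length[e_in]
  # depth of ingroup tips measured from the ingroup attachment node
  tmp <- rooted
  tmp$edge.length[e_out] <- D; tmp$edge.length[e_in] <- 0
  depths <- ape::node.depth.edgelength(tmp)
  in_tips <- setdiff(seq_len(n_tip), out_idx)
  h_in <- mean(depths[in_tips])
  x <- min(max((D - h_in) / 2, 0), D)
  rooted$edge.length[e_in] <- x
  rooted$edge.length[e_out] <- D - x
  rooted
}

#' @export
print.calibrated_tree <- function(x, ...) {
  cat(sprintf("strict-clock calibrated tree: rate %.4g subs/site/MY, %d nodes\n",
              x$rate, nrow(x$ages)))
  cat(sprintf("  root age %.2f MYA\n", max(x$ages$age_mya)))
  invisible(x)
}
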