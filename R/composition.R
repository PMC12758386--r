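# Arm composition matrix, hierarchical arm clustering with bootstrap
# support, and two-step k-means block typing.

#' Build the arm x variant composition matrix
#'
#' Rows are chromosome arms, columns are variant signatures, cells are
#' the count of that variant in the arm divided by the arm's total unit
#' count (computed before any column filtering, so rows sum to at most
#' 1). Arms with fewer than `min_units` units are dropped, as are
#' variants whose genome-wide count is not strictly greater than
#' `min_count`.
#'
#' @param units data.frame with `arm` and `signature` columns.
#' @param min_count Keep variants with genome-wide count > `min_count`
#'   (default 100, the "most abundant" filter).
#' @param min_units Keep arms with at least `min_units` units (default
#'   2000).
#' @return Numeric matrix (arms x signatures); the empty signature is
#'   labeled `"<consensus>"`. Attribute `arm_totals` records pre-filter
#'   unit counts per retained arm.
#' @export
build_matrix <- function(units, min_count = 100L, min_units = 2000L) {
  stopifnot(all(c("arm", "signature") %in% names(units)))
  totals <- table(units$arm)
  keep_arms <- names(totals)[totals >= min_units]
  if (length(keep_arms) == 0L) {
    stop("all arms fall below min_units = ", min_units)
  }
  genome_counts <- table(units$signature)
  keep_sigs <- names(genome_counts)[genome_counts > min_count]
  if (length(keep_sigs) == 0L) {
    stop("no variant exceeds min_count = ", min_count)
  }
  u <- units[units$arm %in% keep_arms, ]
  tab <- table(factor(u$arm, levels = keep_arms),
               factor(u$signature, levels = keep_sigs))
  mat <- sweep(unclass(tab), 1, as.numeric(totals[keep_arms]), "/")
  colnames(mat)[colnames(mat) == ""] <- "<consensus>"
  attr(mat, "arm_totals") <- as.numeric(totals[keep_arms])
  mat
}

#' Cluster arms by variant composition with bootstrap support
#'
#' Hierarchical clustering of the composition-matrix rows with
#' correlation distance (1 - Pearson r) and average linkage. Support for
#' each internal grouping is the percentage of `n_boot` column-resampled
#' replicates (a plain nonparametric bootstrap over variants) whose
#' clustering contains the same group of arms.
#'
#' @param mat Composition matrix from [build_matrix()].
#' @param n_boot Number of bootstrap replicates (default 100).
#' @param seed Seed for the resampling.
#' @return list of class `arm_clustering`: `hclust`, `phylo` (with
#'   `node.label` = support, root = 100), `support`, `newick`.
#' @export
cluster_arms <- function(mat, n_boot = 100L, seed = 1L) {
  if (nrow(mat) < 3L) stop("need at least 3 arms to cluster")
  sds <- apply(mat, 1, stats::sd)
  if (any(sds == 0)) {
    stop("correlation undefined for constant arm profile: ",
         paste(rownames(mat)[sds == 0], collapse = ", "))
  }
  corr_dist <- function(m) stats::as.dist(1 - stats::cor(t(m)))
  hc <- stats::hclust(corr_dist(mat), method = "average")
  phy <- ape::as.phylo(hc)
  boot_trees <- with_seed(seed, {
    lapply(seq_len(n_boot), function(b) {
      repeat {
        cols <- sample.int(ncol(mat), replace = TRUE)
        mb <- mat[, cols, drop = FALSE]
        if (all(apply(mb, 1, stats::sd) > 0)) break
      }
      ape::as.phylo(stats::hclust(corr_dist(mb), method = "average"))
    })
  })
  class(boot_trees) <- "multiPhylo"
  counts <- ape::prop.clades(phy, boot_trees, rooted = TRUE)
  counts[is.na(counts)] <- 0L
  support <- 100 * counts / n_boot
  # the root clade (all arms) is in every replicate by construction
  support[1] <- 100
  phy$node.label <- formatC(support, format = "d")
  structure(
    list(hclust = hc, phylo = phy, support = support,
         newick = ape::write.tree(phy)),
    class = "arm_clustering"
  )
}

#' @export
print.arm_clustering <- function(x, ...) {
  cat("arm composition clustering (correlation distance, average linkage)\n")
  cat(x$newick, "\n")
  invisible(x)
}

#' Two-step k-means classification of higher-order blocks
#'
#' Step 1 clusters variant signatures by their frequency vectors across
#' arms (the columns of the composition matrix); step 2 tiles each cap
#' into fixed-width blocks, represents every block by its composition
#' over the step-1 variant clusters (fractions summing to 1), and
#' clusters the blocks. In both steps k is chosen from `k_range` by the
#' best mean silhouette score (Euclidean distance, k-means with
#' `n_init` random starts).
#'
#' Terminal partial blocks shorter than half the block width are merged
#' into their left neighbour; blocks containing no units are dropped.
#'
#' @param mat Composition matrix from [build_matrix()].
#' @param units data.frame of positioned units (`arm`, `start`, `end`,
#'   `signature`).
#' @param spans data.frame `arm`, `start`, `end` of the regions to tile
#'   into blocks: typically the annotated satellite arrays (so blocks do
#'   not straddle SD spacers), or whole cap spans.
#' @param block_width Block width in bp (20 kbp for real caps, 2 kbp for
#'   the scaled synthetic genomes).
#' @param k_range Length-2 integer range of k to search (default 5..20).
#' @param n_init Random starts per k.
#' @param seed Seed making both k-means steps deterministic.
#' @return list of class `block_typing`: `blocks` (data.frame `arm`,
#'   `start`, `end`, `type`), `variant_clusters` (named step-1 cluster id
#'   per signature), `k1`, `k2`, `silhouette1`, `silhouette2` (mean
#'   silhouette per candidate k).
#' @export
two_step_kmeans <- function(mat, units, spans, block_width = 20000L,
                            k_range = c(5L, 20L), n_init = 10L, seed = 1L) {
  if (nrow(mat) == 0L || ncol(mat) == 0L) stop("empty composition matrix")
  ks <- seq(max(2L, k_range[1]), k_range[2])
  x1 <- t(mat) # variants x arms
  if (nrow(x1) <= min(ks)) {
    stop("fewer variants (", nrow(x1), ") than smallest k (", min(ks), ")")
  }
  if (nrow(unique(x1)) < 2L) {
    stop("all variant frequency vectors identical; silhouette undefined for k > 1")
  }
  s1 <- silhouette_kmeans(x1, ks, n_init, seed)
  variant_clusters <- s1$cluster
  names(variant_clusters) <- rownames(x1)

  # step 2: block composition over step-1 clusters
  sig_cluster <- variant_clusters
  blocks <- tile_blocks(spans, block_width)
  comp <- matrix(0, nrow(blocks), s1$k,
                 dimnames = list(NULL, paste0("c", seq_len(s1$k))))
  sig_of_unit <- units$signature
  sig_of_unit[sig_of_unit == ""] <- "<consensus>"
  ucl <- sig_cluster[sig_of_unit]
  mid <- (units$start + units$end) / 2
  for (i in seq_len(nrow(blocks))) {
    sel <- units$arm == blocks$arm[i] &
      mid >= blocks$start[i] & mid < blocks$end[i]
    cl <- ucl[sel]
    cl <- cl[!is.na(cl)]
    if (length(cl)) {
      tb <- tabulate(cl, nbins = s1$k)
      comp[i, ] <- tb / sum(tb)
    }
  }
  nonempty <- rowSums(comp) > 0
  blocks <- blocks[nonempty, , drop = FALSE]
  comp <- comp[nonempty, , drop = FALSE]
  if (nrow(comp) <= min(ks)) {
    stop("fewer populated blocks (", nrow(comp), ") than smallest k")
  }
  ks2 <- ks[ks < nrow(unique(comp))]
  if (!length(ks2)) {
    stop("block compositions too uniform; silhouette undefined for k > 1")
  }
  s2 <- silhouette_kmeans(comp, ks2, n_init, seed + 1L)
  blocks$type <- s2$cluster
  rownames(blocks) <- NULL
  structure(
    list(blocks = blocks, block_composition = comp,
         variant_clusters = variant_clusters,
         k1 = s1$k, k2 = s2$k,
         silhouette1 = s1$scores, silhouette2 = s2$scores),
    class = "block_typing"
  )
}

# k-means over rows of x for each k in ks; picks k by best mean
# silhouette (Euclidean). Returns the winning clustering.
silhouette_kmeans <- function(x, ks, n_init, seed) {
  ks <- ks[ks < nrow(x)]
  if (!length(ks)) stop("no feasible k below the number of observations")
  d <- stats::dist(x)
  fits <- list()
  scores <- rep(NA_real_, length(ks))
  for (j in seq_along(ks)) {
    fit <- with_seed(seed + ks[j], try(
      stats::kmeans(x, centers = ks[j], nstart = n_init, iter.max = 50L),
      silent = TRUE
    ))
    if (inherits(fit, "try-error")) next
    fits[[j]] <- fit
    sil <- cluster::silhouette(fit$cluster, d)
    scores[j] <- mean(sil[, "sil_width"])
  }
  if (all(is.na(scores))) stop("k-means failed for every k in range")
  best <- which.max(scores)
  list(
    k = ks[best], cluster = fits[[best]]$cluster,
    scores = stats::setNames(scores, ks)
  )
}

# Tile spans into block_width windows; a terminal partial block of
# at least half width stands alone, otherwise it is merged into the
# preceding block.
tile_blocks <- function(spans, block_width) {
  out <- list()
  for (i in seq_len(nrow(spans))) {
    s <- spans$start[i]; e <- spans$end[i]
    starts <- seq(s, e - 1L, by = block_width)
    ends <- pmin(starts + block_width, e)
    n <- length(starts)
    if (n > 1L && (ends[n] - starts[n]) < block_width / 2) {
      ends[n - 1L] <- ends[n]
      starts <- starts[-n]; ends <- ends[-n]
    }
    out[[i]] <- data.frame(arm = spans$arm[i], start = starts, end = ends)
  }
  do.call(rbind, out)
}
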