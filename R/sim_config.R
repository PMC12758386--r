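#' Configuration for the cap-genome simulator
#'
#' Describes the synthetic study conditions: chromosome arms made of a
#' euchromatic flank followed by a subterminal cap of tandem satellite
#' arrays interdigitated with SD-spacer copies, ending at the telomere.
#' Dimensions are desk-scale by design (2 kbp spacers standing in for the
#' 32-34 kbp real copies, 2 kbp higher-order blocks for the 20 kbp real
#' ones, 20 kbp boundary windows for the 2 Mbp real ones); every size is a
#' parameter, never a constant.
#'
#' Satellite variation is drawn from a small alphabet of unit variants
#' (signatures relative to the consensus). Each array carries one of
#' `n_block_types` composition types (a frequency vector over variants);
#' each arm favours particular types, which gives arms distinguishable
#' composition profiles. Spacer copies evolve along `spacer_tree` by
#' per-site Poisson substitutions only, so their true alignment is the
#' identity and tree ground truth is exact.
#'
#' @param seed Integer seed; the whole simulation is a deterministic
#'   function of the config including this seed.
#' @param n_arms Number of chromosome arms.
#' @param arm_names Optional names, default `sim.h1.chr<i>q`.
#' @param flank_length Euchromatic flank length in bp.
#' @param units_per_array Integer range `c(lo, hi)` of satellite units per
#'   array.
#' @param arrays_per_cap Integer range `c(lo, hi)` of arrays per cap.
#' @param unit_consensus Consensus unit sequence (default the packaged
#'   32-mer).
#' @param variants Character vector of canonical variant signatures; the
#'   first should usually be `""` (the consensus itself). `NULL` draws
#'   `n_variants` default substitution/deletion variants.
#' @param n_variants Number of default variants when `variants` is `NULL`
#'   (default 8: four pairs of block-type-defining variants).
#' @param n_block_types Number of array composition types.
#' @param type_profiles `n_block_types x n_variants` matrix, rows summing
#'   to 1: variant frequencies within each block type.
#' @param arm_type_weights `n_arms x n_block_types` matrix, rows summing
#'   to 1: per-arm mixing weights over block types.
#' @param block_width Higher-order block width in bp.
#' @param spacer_length Spacer copy length in bp.
#' @param spacer_tree Optional rooted `phylo` with branch lengths in
#'   substitutions/site for the spacer duplication history; `NULL` draws a
#'   coalescent tree scaled to `spacer_tree_depth`.
#' @param spacer_tree_depth Root-to-tip depth (subs/site) of the default
#'   spacer tree.
#' @param exchange_events List of ectopic exchange events, each a list
#'   with `arm_a`, `arm_b` and `placement` (`"in_spacer"` or `"uniform"`),
#'   or explicit `pos_a`/`pos_b`.
#' @param meth Beta-binomial methylation parameters: means and
#'   concentrations for satellite, spacer and flank CpGs plus per-strand
#'   mean `coverage` (set a concentration to `Inf` for noise-free
#'   per-site means).
#' @param boundary Boundary-feature parameters: window `width` (bp),
#'   enrichment `fold`, base densities `sd_per_kb`/`gene_per_kb` and
#'   length ranges `sd_len`/`gene_len`.
#' @return A validated object of class `sim_config`.
#' @seealso [simulate_cap_genome()]
#' @export
sim_config <- function(seed = 1L,
                       n_arms = 6L,
                       arm_names = NULL,
                       flank_length = 60000L,
                       units_per_array = c(60L, 120L),
                       arrays_per_cap = c(6L, 10L),
                       unit_consensus = stcap_consensus(),
                       variants = NULL,
                       n_variants = 8L,
                       n_block_types = 4L,
                       type_profiles = NULL,
                       arm_type_weights = NULL,
                       block_width = 2000L,
                       spacer_length = 2000L,
                       spacer_tree = NULL,
                       spacer_tree_depth = 0.05,
                       exchange_events = list(),
                       meth = list(),
                       boundary = list()) {
  if (!grepl("^[ACGTacgt]+$", unit_consensus)) {
    stop("unit_consensus must contain only A, C, G, T")
  }
  unit_consensus <- toupper(unit_consensus)
  stopifnot(
    n_arms >= 1L, flank_length > 0L,
    length(units_per_array) == 2L, all(units_per_array > 0L),
    length(arrays_per_cap) == 2L, all(arrays_per_cap > 0L),
    block_width > 0L, spacer_length > 0L, spacer_tree_depth >= 0
  )
  if (is.null(arm_names)) {
    arm_names <- sprintf("sim.h1.chr%dq", seq_len(n_arms))
  }
  stopifnot(length(arm_names) == n_arms, !anyDuplicated(arm_names))

  defaults <- with_seed(seed, {
    v <- variants
    if (is.null(v)) v <- default_variants(unit_consensus, n_variants)
    tp <- type_profiles
    if (is.null(tp)) tp <- default_type_profiles(n_block_types, length(v))
    aw <- arm_type_weights
    if (is.null(aw)) aw <- default_arm_weights(n_arms, nrow(tp))
    list(variants = v, type_profiles = tp, arm_type_weights = aw)
  })
  variants <- vapply(defaults$variants, normalize_signature,
                     character(1), consensus = unit_consensus)
  variants <- unname(variants)
  if (anyDuplicated(variants)) stop("variant signatures are not distinct")
  type_profiles <- defaults$type_profiles
  arm_type_weights <- defaults$arm_type_weights

  if (length(variants) == 0L) stop("variant profile must not be empty")
  stopifnot(
    ncol(type_profiles) == length(variants),
    nrow(arm_type_weights) == n_arms,
    ncol(arm_type_weights) == nrow(type_profiles)
  )
  if (any(abs(rowSums(type_profiles) - 1) > 1e-9)) {
    stop("type_profiles rows must sum to 1")
  }
  if (any(abs(rowSums(arm_type_weights) - 1) > 1e-9)) {
    stop("arm_type_weights rows must sum to 1")
  }
  if (any(type_profiles < 0) || any(arm_type_weights < 0)) {
    stop("profile frequencies must be non-negative")
  }
  if (!is.null(spacer_tree)) {
    stopifnot(inherits(spacer_tree, "phylo"))
    if (any(spacer_tree$edge.length < 0)) {
      stop("spacer_tree branch lengths must be >= 0")
    }
  }

  meth <- utils::modifyList(list(
    sat_mean = 0.80, sat_conc = 30,
    spacer_mean = 0.35, spacer_conc = 30,
    flank_mean = 0.70, flank_conc = 30,
    coverage = 20
  ), meth)
  boundary <- utils::modifyList(list(
    width = 20000L, fold = 5,
    sd_per_kb = 0.08, gene_per_kb = 0.08,
    sd_len = c(500L, 2000L), gene_len = c(300L, 1500L)
  ), boundary)
  stopifnot(boundary$width < flank_length)

  # per-arm variant profile implied by the type mixture; rows sum to 1
  arm_variant_profiles <- arm_type_weights %*% type_profiles
  rownames(arm_variant_profiles) <- arm_names

  structure(
    list(
      seed = as.integer(seed), n_arms = as.integer(n_arms),
      arm_names = arm_names, flank_length = as.integer(flank_length),
      units_per_array = as.integer(units_per_array),
      arrays_per_cap = as.integer(arrays_per_cap),
      unit_consensus = unit_consensus,
      variants = variants,
      type_profiles = type_profiles,
      arm_type_weights = arm_type_weights,
      arm_variant_profiles = arm_variant_profiles,
      block_width = as.integer(block_width),
      spacer_length = as.integer(spacer_length),
      spacer_tree = spacer_tree,
      spacer_tree_depth = spacer_tree_depth,
      exchange_events = exchange_events,
      meth = meth, boundary = boundary
    ),
    class = "sim_config"
  )
}

# Default variant alphabet: the consensus plus substitution variants (and
# one single-base deletion variant when n >= 5) at distinct positions.
default_variants <- function(consensus, n) {
  stopifnot(n >= 1L)
  L <- nchar(consensus)
  out <- ""
  if (n == 1L) return(out)
  pos <- sample.int(L - 2L, n - 1L) + 1L # avoid first/last base
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(n - 1L)) {
    p <- pos[i]
    ref <- substr(consensus, p, p)
    if (i == 4L) {
      sig <- sprintf("%ddel%s", p, ref)
    } else {
      alt <- sample(setdiff(bases, ref), 1L)
      sig <- sprintf("%d%s>%s", p, ref, alt)
      # every other variant carries a second substitution
      if (i %% 2L == 0L) {
        p2 <- pos[(i %% (n - 1L)) + 1L]
        if (p2 != p) {
          ref2 <- substr(consensus, p2, p2)
          alt2 <- sample(setdiff(bases, ref2), 1L)
          ed <- rbind(
            data.frame(pos = p, class = "SUB", ref = ref, alt = alt),
            data.frame(pos = p2, class = "SUB", ref = ref2, alt = alt2)
          )
          sig <- canonical_signature(ed)
        }
      }
    }
    out <- c(out, sig)
  }
  unique(out)[seq_len(min(n, length(unique(out))))]
}

# Block-type composition profiles. With enough variants each type loads
# 0.42 on each of two dedicated major variants (so step-1 clustering has
# crisp variant groups); otherwise 0.65 on a single major.
default_type_profiles <- function(n_types, n_variants) {
  stopifnot(n_types <= n_variants)
  if (n_variants >= 2L * n_types) {
    tp <- matrix(0.16 / (n_variants - 2L), n_types, n_variants)
    for (t in seq_len(n_types)) tp[t, c(2L * t - 1L, 2L * t)] <- 0.42
  } else {
    tp <- matrix(0.35 / (n_variants - 1L), n_types, n_variants)
    for (t in seq_len(n_types)) tp[t, t] <- 0.65
  }
  tp / rowSums(tp)
}

# Arm mixing over block types: each arm favours one type.
default_arm_weights <- function(n_arms, n_types) {
  if (n_types == 1L) return(matrix(1, n_arms, 1L))
  aw <- matrix(0.45 / (n_types - 1), n_arms, n_types)
  for (a in seq_len(n_arms)) aw[a, ((a - 1L) %% n_types) + 1L] <- 0.55
  aw / rowSums(aw)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    paste0(
      "cap-genome simulation config (seed %d)\n",
      "  %d arms, flank %d bp, %d-%d arrays/cap, %d-%d units/array\n",
      "  %d unit variants, %d block types, block %d bp, spacer %d bp\n",
      "  %d exchange event(s)\n"
    ),
    x$seed, x$n_arms, x$flank_length,
    x$arrays_per_cap[1], x$arrays_per_cap[2],
    x$units_per_array[1], x$units_per_array[2],
    length(x$variants), nrow(x$type_profiles), x$block_width,
    x$spacer_length, length(x$exchange_events)
  ))
  invisible(x)
}
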