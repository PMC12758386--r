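#' Run the full cap analysis pipeline on a set of arm sequences
#'
#' Strings the modules together the way the per-species analyses run:
#' satellite unit detection and typing, array/spacer derivation,
#' composition matrix, arm clustering, two-step block typing, all-vs-all
#' nonallelic arm alignment with exchange-candidate detection and the
#' breakpoint permutation test, spacer MSA with NJ tree and the RF shift
#' test, and (when methylation calls are given) CpG merging and
#' compartment profiling.
#'
#' @param sequences Named `DNAStringSet`/character vector of arm
#'   sequences.
#' @param consensus A [consensus_model()].
#' @param block_width Higher-order block width (bp).
#' @param k_range k search range for [two_step_kmeans()].
#' @param min_units,min_count Composition-matrix filters (scaled for the
#'   input; see [build_matrix()]).
#' @param max_gap Array merging distance (bp).
#' @param min_span Candidate span threshold for [detect_candidates()].
#' @param window Anchor chaining window for [pairwise_identity()].
#' @param boundary_width Boundary window width (bp).
#' @param methylation Optional bedMethyl-like calls data.frame.
#' @param n_boot Bootstrap replicates for trees/arm clustering.
#' @param n_perm Permutations for the interval tests.
#' @param seed Master seed; each stochastic stage derives its own
#'   offset from it.
#' @return list of stage reports: `annotation`, `matrix`, `arm_tree`,
#'   `blocks`, `alignment_blocks`, `candidates`, `breakpoint_test`,
#'   `spacer_alignment`, `spacer_tree`, `rf_shift`, `boundary_windows`,
#'   `methylation` (sites/profile or NULL).
#' @export
run_cap_pipeline <- function(sequences,
                             consensus = consensus_model(),
                             block_width = 2000L,
                             k_range = c(2L, 8L),
                             min_units = 500L,
                             min_count = 50L,
                             max_gap = 5L,
                             min_span = 10000L,
                             window = 50000L,
                             boundary_width = 20000L,
                             methylation = NULL,
                             n_boot = 100L,
                             n_perm = 1000L,
                             seed = 1L) {
  arms <- names(sequences)
  ann <- annotate_genome(sequences, consensus, max_gap = max_gap)
  mat <- build_matrix(ann$units, min_count = min_count, min_units = min_units)
  arm_tree <- if (nrow(mat) >= 3L) cluster_arms(mat, n_boot = n_boot, seed = seed) else NULL
  blocks <- two_step_kmeans(mat, ann$units, ann$arrays,
                            block_width = block_width, k_range = k_range,
                            seed = seed + 1L)

  # all-vs-all nonallelic alignment
  aln_blocks <- list()
  for (i in seq_len(length(arms) - 1L)) {
    for (j in (i + 1L):length(arms)) {
      aln_blocks[[length(aln_blocks) + 1L]] <- pairwise_identity(
        as.character(sequences[[arms[i]]]), as.character(sequences[[arms[j]]]),
        window = window, arm_a = arms[i], arm_b = arms[j]
      )
    }
  }
  aln_blocks <- do.call(rbind, aln_blocks)
  candidates <- detect_candidates(aln_blocks, min_span = min_span)

  caps <- do.call(rbind, lapply(arms, function(a) {
    u <- ann$units[ann$units$arm == a, ]
    if (nrow(u) == 0L) return(NULL)
    data.frame(arm = a, start = min(u$start), end = max(u$end))
  }))
  bp_test <- NULL
  if (nrow(candidates) > 0L && !is.null(ann$spacers)) {
    bps <- rbind(
      data.frame(arm = candidates$arm_a, pos = candidates$breakpoint_a),
      data.frame(arm = candidates$arm_b, pos = candidates$breakpoint_b)
    )
    # keep breakpoints that fall inside an annotated cap
    keep <- vapply(seq_len(nrow(bps)), function(r) {
      cap <- caps[caps$arm == bps$arm[r], ]
      nrow(cap) == 1L && bps$pos[r] >= cap$start && bps$pos[r] < cap$end
    }, logical(1))
    bps <- bps[keep, , drop = FALSE]
    if (nrow(bps) > 0L) {
      bp_test <- breakpoint_spacer_test(bps, ann$spacers, caps,
                                        n_perm = n_perm, seed = seed + 2L)
    }
  }

  # spacer phylogeny + RF shift on the extracted spacer copies
  spacer_aln <- NULL; spacer_tree <- NULL; rf <- NULL
  if (!is.null(ann$spacers) && nrow(ann$spacers) >= 4L) {
    sp_seqs <- character(nrow(ann$spacers))
    names(sp_seqs) <- sprintf("%s_sp%02d", ann$spacers$arm,
                              stats::ave(seq_len(nrow(ann$spacers)),
                                         ann$spacers$arm, FUN = seq_along))
    for (r in seq_len(nrow(ann$spacers))) {
      s <- as.character(sequences[[ann$spacers$arm[r]]])
      sp_seqs[r] <- substr(s, ann$spacers$start[r] + 1L, ann$spacers$end[r])
    }
    spacer_aln <- align_spacers(sp_seqs)
    if (length(spacer_aln) >= 4L) {
      spacer_tree <- nj_tree(spacer_aln, n_boot = n_boot, seed = seed + 3L)
      rf <- rf_shift_test(spacer_aln, n_boot = max(n_boot, 200L),
                          seed = seed + 4L)
    }
  }

  bw <- boundary_windows(caps, setNames(nchar(as.character(sequences)), arms),
                         width = boundary_width)
  meth <- NULL
  if (!is.null(methylation)) {
    sites <- merge_cpg(methylation, sequences = sequences)
    feats <- list()
    # spacers first: the per-interval length/methylation correlation
    # is computed on the first class
    if (!is.null(ann$spacers)) feats$spacer <- ann$spacers
    if (!is.null(ann$arrays)) feats$satellite <- ann$arrays
    feats <- feats[lengths(feats) > 0]
    prof <- if (length(feats) >= 1L) {
      methylation_profile(sites, feats, boundaries = bw)
    } else NULL
    meth <- list(sites = sites, profile = prof)
  }

  list(
    annotation = ann, matrix = mat, arm_tree = arm_tree, blocks = blocks,
    alignment_blocks = aln_blocks, candidates = candidates,
    breakpoint_test = bp_test, spacer_alignment = spacer_aln,
    spacer_tree = spacer_tree, rf_shift = rf,
    boundary_windows = bw, methylation = meth
  )
}
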