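test_that("pairwise_identity: self, planted segment, strand symmetry", {
  set.seed(1)
  s <- random_dna(20000)
  b <- pairwise_identity(s, s)
  expect_equal(nrow(b), 1L)
  expect_equal(b$start_a, 0L)
  expect_equal(b$end_a, 20000L)
  expect_equal(b$identity, 1)
  expect_equal(b$orientation, "+")

  # 10 kbp shared segment at ~99.9% identity inside divergent flanks
  seg <- random_dna(10000)
  armA <- paste0(random_dna(6000), seg, random_dna(4000))
  armB <- paste0(random_dna(3000), mutate_seq(seg, 0.001), random_dna(5000))
  b2 <- pairwise_identity(armA, armB)
  big <- b2[which.max(b2$end_a - b2$start_a), ]
  expect_gte(big$end_a - big$start_a, 0.95 * 10000)
  expect_true(big$start_a >= 5900 && big$end_a <= 16100)
  expect_lt(abs(big$identity - 0.999), 0.001)

  # reverse-complementing arm B flips orientation, mirrors coordinates
  rcB <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(armB)))
  b3 <- pairwise_identity(armA, rcB)
  big3 <- b3[which.max(b3$end_a - b3$start_a), ]
  expect_equal(big3$orientation, "-")
  expect_equal(big3$start_a, big$start_a)
  expect_equal(nchar(armB) - big3$end_b, big$start_b)

  # no anchors -> empty
  expect_equal(nrow(pairwise_identity(strrep("A", 100), strrep("C", 100))), 0L)
})

test_that("detect_candidates finds planted copy-type exchanges", {
  cfg <- sim_config(
    seed = 11L, n_arms = 4L, flank_length = 40000L,
    units_per_array = c(100L, 160L), arrays_per_cap = c(6L, 8L),
    exchange_events = list(list(
      arm_a = "sim.h1.chr1q", arm_b = "sim.h1.chr3q",
      placement = "in_spacer", mode = "copy", spacer_index = 1L
    ))
  )
  sim <- simulate_cap_genome(cfg)
  bp <- sim$truth$breakpoints
  blocks <- pairwise_identity(
    as.character(sim$sequences[["sim.h1.chr1q"]]),
    as.character(sim$sequences[["sim.h1.chr3q"]]),
    arm_a = "sim.h1.chr1q", arm_b = "sim.h1.chr3q"
  )
  cand <- detect_candidates(blocks, min_span = 10000L)
  expect_equal(nrow(cand), 1L)
  expect_lte(abs(cand$breakpoint_a - bp$pos_a), 100L)
  expect_lte(abs(cand$breakpoint_b - bp$pos_b), 100L)
  expect_equal(cand$identity_class, ">99.8%")

  # nothing above the identity bar -> empty
  none <- detect_candidates(blocks[blocks$identity < 0.99, , drop = FALSE],
                            min_span = 1000L)
  expect_equal(nrow(none), 0L)
})

test_that("breakpoint_spacer_test boundary case and invariances", {
  caps <- data.frame(arm = c("a1", "a2"), start = 0L, end = 50000L)
  spacers <- rbind(
    data.frame(arm = "a1", start = c(10000L, 30000L), end = c(12000L, 32000L)),
    data.frame(arm = "a2", start = 20000L, end = 22000L)
  )
  inside <- data.frame(arm = c("a1", "a2"), pos = c(10500L, 21000L))
  r <- breakpoint_spacer_test(inside, spacers, caps, n_perm = 200L, seed = 1L)
  expect_equal(r$observed, 0)
  expect_equal(r$p, (1 + sum(r$null <= 0)) / (1 + 200))
  expect_gt(r$p, 0) # add-one correction: never zero

  # invariant to cap/breakpoint ordering
  r2 <- breakpoint_spacer_test(inside[2:1, ], spacers, caps[2:1, ],
                               n_perm = 200L, seed = 1L)
  expect_equal(r2$observed, r$observed)
  expect_error(breakpoint_spacer_test(inside, spacers[0, ], caps), "empty spacer")
})

test_that("breakpoint test is calibrated under the null and powered", {
  caps <- data.frame(arm = paste0("a", 1:4), start = 0L, end = 100000L)
  spacers <- do.call(rbind, lapply(1:4, function(i) {
    data.frame(arm = paste0("a", i),
               start = seq(10000L, 90000L, by = 20000L),
               end = seq(10000L, 90000L, by = 20000L) + 2000L)
  }))
  set.seed(30)
  p_null <- replicate(60, {
    bps <- data.frame(arm = sample(caps$arm, 5, replace = TRUE),
                      pos = sample.int(100000L, 5) - 1L)
    breakpoint_spacer_test(bps, spacers, caps, n_perm = 200L,
                           seed = sample.int(1e6, 1))$p
  })
  expect_lt(abs(mean(p_null <= 0.05) - 0.05), 0.08)
  p_alt <- replicate(20, {
    arms <- sample(caps$arm, 5, replace = TRUE)
    pos <- vapply(arms, function(a) {
      sp <- spacers[spacers$arm == a, ]
      i <- sample.int(nrow(sp), 1L)
      sp$start[i] + sample.int(2000L, 1L) - 1L
    }, numeric(1))
    breakpoint_spacer_test(data.frame(arm = arms, pos = pos), spacers, caps,
                           n_perm = 200L, seed = sample.int(1e6, 1))$p
  })
  expect_gte(mean(p_alt <= 0.05), 0.9)
})

test_that("RF distance matches bipartition enumeration", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(rf_distance(t1, t1), 0)
  expect_equal(oracle_rf(t1, t1), 0)
  # the two distinct resolved 4-taxon topologies differ by both their
  # internal bipartitions
  expect_equal(rf_distance(t1, t2), 2)
  expect_equal(oracle_rf(t1, t2), 2)
  # symmetric + triangle inequality on sampled triples
  set.seed(5)
  for (i in 1:5) {
    a <- ape::rtree(7); b <- ape::rtree(7); c <- ape::rtree(7)
    b$tip.label <- a$tip.label; c$tip.label <- a$tip.label
    expect_equal(rf_distance(a, b), rf_distance(b, a))
    expect_equal(rf_distance(a, b), oracle_rf(a, b))
    expect_lte(rf_distance(a, c), rf_distance(a, b) + rf_distance(b, c))
  }
})

test_that("rf_shift_test: clean alignments do not shift, chimeras do", {
  set.seed(8)
  tr <- ape::rcoal(8)
  tr$edge.length <- tr$edge.length /
    max(ape::node.depth.edgelength(tr)[1:8]) * 0.05
  seqs <- stcap:::evolve_tree_seqs(tr, random_dna(2000))
  r <- rf_shift_test(seqs, n_boot = 100L, seed = 1L)
  expect_gte(r$p_first, 0.05)
  expect_gte(r$p_second, 0.05)
  expect_true(all(r$null >= 0))

  # chimera: halves from maximally different topologies
  trA <- tr
  repeat {
    trB <- ape::rtree(8)
    trB$tip.label <- sample(trA$tip.label)
    trB$edge.length <- trB$edge.length /
      max(ape::node.depth.edgelength(trB)[1:8]) * 0.05
    if (rf_distance(trA, trB) >= 8) break
  }
  root <- random_dna(2000)
  sA <- stcap:::evolve_tree_seqs(trA, substr(root, 1, 1000))
  sB <- stcap:::evolve_tree_seqs(trB, substr(root, 1001, 2000))
  chim <- paste0(sA, sB[names(sA)])
  names(chim) <- names(sA)
  r2 <- rf_shift_test(chim, n_boot = 200L, seed = 2L)
  expect_lt(min(r2$p_first, r2$p_second), 0.01)
  expect_error(rf_shift_test(seqs[1:3]), "at least 4")
})

test_that("allelic identity profile separates haplotype divergence", {
  set.seed(9)
  arms <- paste0("chr", 1:3, "q")
  h1 <- stats::setNames(lapply(1:3, function(i) random_dna(12000)), arms)
  # allelic partners: 1% divergence; nonallelic pairs are unrelated
  h2 <- stats::setNames(lapply(h1, function(s) mutate_seq(s, 0.01)), arms)
  amap <- data.frame(arm1 = arms, arm2 = arms)
  prof <- allelic_identity_profile(h1, h2, amap, window = 4000L,
                                   n_perm = 200L, seed = 1L)
  al <- prof$pair_identity
  expect_equal(sum(al$allelic), 3L)
  # 1% substitution -> ~0.99 identity, within 0.2%
  expect_lt(abs(mean(al$identity[al$allelic], na.rm = TRUE) - 0.99), 0.002)
  expect_true(all(is.na(al$identity[!al$allelic])))

  # identical haplotypes give all windows 1.0
  prof2 <- allelic_identity_profile(h1, h1, amap, window = 4000L,
                                    n_perm = 50L, seed = 1L)
  w <- prof2$windows
  expect_true(all(w$identity[w$allelic] == 1))
  expect_error(
    allelic_identity_profile(h1, h2, amap, window = 50000L),
    "window larger"
  )
})
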