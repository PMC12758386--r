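small_cfg <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_arms = 2L, flank_length = 8000L,
             units_per_array = c(30L, 50L), arrays_per_cap = c(3L, 4L),
             boundary = list(width = 3000L), ...)
}

test_that("zero-divergence config emits the consensus everywhere", {
  cfg <- sim_config(
    seed = 3L, n_arms = 1L, flank_length = 2000L,
    units_per_array = c(20L, 20L), arrays_per_cap = c(2L, 2L),
    variants = "", n_block_types = 1L,
    type_profiles = matrix(1, 1, 1), arm_type_weights = matrix(1, 1, 1),
    boundary = list(width = 1000L)
  )
  sim <- simulate_cap_genome(cfg)
  u <- sim$truth$units
  s <- as.character(sim$sequences[[1]])
  units_seq <- substring(s, u$start + 1L, u$end)
  expect_true(all(units_seq == stcap_consensus()))
  expect_true(all(u$signature == ""))
})

test_that("simulation is deterministic in the seed and changes with it", {
  a <- simulate_cap_genome(small_cfg(7L))
  b <- simulate_cap_genome(small_cfg(7L))
  c <- simulate_cap_genome(small_cfg(8L))
  expect_identical(as.character(a$sequences), as.character(b$sequences))
  expect_identical(a$truth$units, b$truth$units)
  expect_false(identical(as.character(a$sequences), as.character(c$sequences)))
  m1 <- simulate_methylation(a)
  m2 <- simulate_methylation(b)
  expect_identical(m1, m2)
})

test_that("truth intervals are coherent", {
  sim <- simulate_cap_genome(small_cfg(5L))
  tr <- sim$truth
  for (arm in names(sim$sequences)) {
    u <- tr$units[tr$units$arm == arm, ]
    sp <- tr$spacers[tr$spacers$arm == arm, ]
    # units non-overlapping and inside the cap
    expect_true(all(u$start[-1] >= u$end[-nrow(u)]))
    cap <- tr$caps[tr$caps$arm == arm, ]
    expect_true(all(u$start >= cap$start & u$end <= cap$end))
    # spacers disjoint from units
    if (nrow(sp)) {
      for (r in seq_len(nrow(sp))) {
        expect_false(any(u$start < sp$end[r] & u$end > sp$start[r]))
      }
    }
    # arrays + spacers tile the cap
    covered <- sum(tr$arrays$end[tr$arrays$arm == arm] -
                     tr$arrays$start[tr$arrays$arm == arm]) +
      sum(sp$end - sp$start)
    expect_equal(covered, cap$end - cap$start)
  }
})

test_that("emitted spacer divergence matches a per-site simulation oracle", {
  # two copies at total distance 0.10 subs/site
  two_leaf <- ape::read.tree(text = "(a:0.05,b:0.05);")
  cfg <- sim_config(seed = 11L, n_arms = 1L, flank_length = 2000L,
                    units_per_array = c(10L, 10L), arrays_per_cap = c(3L, 3L),
                    spacer_length = 2000L, spacer_tree = two_leaf,
                    boundary = list(width = 500L))
  sim <- simulate_cap_genome(cfg)
  sp <- sim$truth$spacers
  s <- as.character(sim$sequences[[1]])
  s1 <- substring(s, sp$start[1] + 1L, sp$end[1])
  s2 <- substring(s, sp$start[2] + 1L, sp$end[2])
  p_obs <- mean(strsplit(s1, "")[[1]] != strsplit(s2, "")[[1]])
  # independent per-site oracle: Poisson(0.05) jump events per branch,
  # uniform among the three other bases; estimated once with 2e5 sites
  # and frozen: E[p] = 0.0938 (matches 3/4 * (1 - exp(-4/3 * 0.1)))
  p_exp <- 0.0938
  tol <- 3 * sqrt(p_exp * (1 - p_exp) / 2000)
  expect_lt(abs(p_obs - p_exp), tol)
})

test_that("per-arm variant frequencies follow the configured profile", {
  # single block type, so arm units are i.i.d. from the arm profile
  fails <- 0L
  for (seed in 1:20) {
    cfg <- sim_config(seed = seed, n_arms = 1L, flank_length = 2000L,
                      units_per_array = c(500L, 500L),
                      arrays_per_cap = c(10L, 10L),
                      n_block_types = 1L, boundary = list(width = 500L))
    sim <- simulate_cap_genome(cfg)
    counts <- table(factor(sim$truth$units$variant_id,
                           levels = seq_along(cfg$variants)))
    p <- stats::chisq.test(counts, p = cfg$arm_variant_profiles[1, ])$p.value
    if (p < 0.01) fails <- fails + 1L
  }
  expect_lte(fails, 1L)
})

test_that("spacer divergence increases with tree path length", {
  cfg <- sim_config(seed = 13L, n_arms = 2L, flank_length = 2000L,
                    units_per_array = c(10L, 10L), arrays_per_cap = c(7L, 7L),
                    boundary = list(width = 500L))
  sim <- simulate_cap_genome(cfg)
  sp <- sim$truth$spacers
  expect_gte(nrow(sp), 10L)
  seqs <- character(nrow(sp))
  for (r in seq_len(nrow(sp))) {
    s <- as.character(sim$sequences[[sp$arm[r]]])
    seqs[r] <- substring(s, sp$start[r] + 1L, sp$end[r])
  }
  coph <- ape::cophenetic.phylo(sim$truth$spacer_tree)
  pd <- c(); tl <- c()
  for (i in seq_len(nrow(sp) - 1L)) for (j in (i + 1L):nrow(sp)) {
    pd <- c(pd, mean(strsplit(seqs[i], "")[[1]] != strsplit(seqs[j], "")[[1]]))
    tl <- c(tl, coph[sp$leaf[i], sp$leaf[j]])
  }
  expect_gt(stats::cor(pd, tl, method = "spearman"), 0.9)
})

test_that("methylation table matches compartment means and edge cases", {
  cfg <- sim_config(seed = 17L, n_arms = 2L, flank_length = 8000L,
                    units_per_array = c(150L, 200L), arrays_per_cap = c(4L, 5L),
                    boundary = list(width = 3000L),
                    meth = list(sat_conc = Inf, spacer_conc = Inf,
                                flank_conc = Inf, coverage = 30))
  sim <- simulate_cap_genome(cfg)
  mc <- simulate_methylation(sim)
  tru <- attr(mc, "truth")
  sat <- tru[tru$class == "satellite", ]
  expect_gte(nrow(sat), 1000L)
  # with infinite concentration every satellite CpG has p = sat_mean;
  # the empirical modified fraction converges by the law of large numbers
  key <- paste(mc$chrom, ifelse(mc$strand == "-", mc$start - 1L, mc$start))
  sat_rows <- key %in% paste(sat$chrom, sat$start)
  emp <- sum(mc$n_mod[sat_rows]) / sum(mc$n_total[sat_rows])
  expect_lt(abs(emp - cfg$meth$sat_mean), 0.02)

  # spacer mean 0 -> all spacer counts zero
  cfg0 <- small_cfg(18L, meth = list(spacer_mean = 0))
  sim0 <- simulate_cap_genome(cfg0)
  mc0 <- simulate_methylation(sim0)
  tru0 <- attr(mc0, "truth")
  spc <- tru0[tru0$class == "spacer", ]
  key0 <- paste(mc0$chrom, ifelse(mc0$strand == "-", mc0$start - 1L, mc0$start))
  expect_true(all(mc0$n_mod[key0 %in% paste(spc$chrom, spc$start)] == 0L))

  # no CpG -> empty table
  no_cpg <- structure(
    list(sequences = Biostrings::DNAStringSet(c(x = "ATATATATAT")),
         truth = list(arrays = data.frame(arm = character(), start = integer(),
                                          end = integer()),
                      spacers = data.frame(arm = character(), start = integer(),
                                           end = integer())),
         config = cfg),
    class = "cap_sim"
  )
  expect_equal(nrow(simulate_methylation(no_cpg, seed = 1L)), 0L)
})

test_that("plant_exchange swaps tails, conserves bp, and honors placement", {
  sim <- simulate_cap_genome(small_cfg(19L))
  arms <- names(sim$sequences)
  len_before <- sum(Biostrings::width(sim$sequences))

  # swap at identical offsets on identical sequences changes nothing
  sim_dup <- sim
  sim_dup$sequences <- Biostrings::DNAStringSet(
    stats::setNames(rep(as.character(sim$sequences[[1]]), 2), arms)
  )
  cap1 <- sim$truth$caps[1, ]
  sim_dup$truth$caps <- data.frame(arm = arms, start = cap1$start, end = cap1$end)
  pos <- cap1$start + 100L
  out <- plant_exchange(sim_dup, list(arm_a = arms[1], arm_b = arms[2],
                                      pos_a = pos, pos_b = pos))
  expect_identical(as.character(out$sequences[[1]]),
                   as.character(out$sequences[[2]]))

  # in_spacer placement lands strictly inside a truth spacer interval
  ev <- list(arm_a = arms[1], arm_b = arms[2], placement = "in_spacer")
  out2 <- plant_exchange(sim, ev, seed = 5L)
  bp <- out2$truth$breakpoints
  sp_before <- sim$truth$spacers
  for (r in seq_len(nrow(bp))) {
    sp_arm <- sp_before[sp_before$arm == bp$arm_a[r], ]
    expect_true(any(bp$pos_a[r] > sp_arm$start & bp$pos_a[r] < sp_arm$end))
  }
  # reciprocal swap conserves total length
  expect_equal(sum(Biostrings::width(out2$sequences)), len_before)
  # breakpoint outside the cap errors
  expect_error(
    plant_exchange(sim, list(arm_a = arms[1], arm_b = arms[2],
                             pos_a = 10L, pos_b = 10L)),
    "outside cap"
  )
})

test_that("copy-mode exchange leaves an identical nonallelic tail pair", {
  sim <- simulate_cap_genome(small_cfg(23L))
  arms <- names(sim$sequences)
  out <- plant_exchange(sim, list(arm_a = arms[1], arm_b = arms[2],
                                  placement = "in_spacer", mode = "copy",
                                  spacer_index = 1L), seed = 9L)
  bp <- out$truth$breakpoints
  sa <- as.character(out$sequences[[arms[1]]])
  sb <- as.character(out$sequences[[arms[2]]])
  expect_identical(substring(sa, bp$pos_a + 1L, nchar(sa)),
                   substring(sb, bp$pos_b + 1L, nchar(sb)))
  # donor arm untouched
  expect_identical(sb, as.character(sim$sequences[[arms[2]]]))
})

test_that("write_cap_sim emits FASTA, BED and JSON sidecar", {
  sim <- simulate_cap_genome(small_cfg(29L))
  dir <- withr::local_tempdir()
  files <- write_cap_sim(sim, dir, methylation = simulate_methylation(sim))
  expect_true(all(file.exists(files)))
  fa <- Biostrings::readDNAStringSet(file.path(dir, "arms.fasta"))
  expect_identical(as.character(fa), as.character(sim$sequences))
  side <- jsonlite::read_json(file.path(dir, "sim.json"))
  expect_equal(side$consensus, stcap_consensus())
})
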