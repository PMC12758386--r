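test_that("center-star alignment round-trips and respects the length filter", {
  set.seed(1)
  base <- random_dna(500)
  seqs <- c(a = base, b = mutate_seq(base, 0.03), c = mutate_seq(base, 0.03))
  aln <- align_spacers(seqs)
  # substitution-only copies: no gap columns, width = input length
  expect_true(all(Biostrings::width(aln) == 500L))
  expect_identical(as.character(aln), seqs)

  # identical sequences align to themselves
  same <- c(x = base, y = base)
  expect_identical(as.character(align_spacers(same)), same)

  # the >90%-of-modal-length filter
  short <- c(seqs, d = substr(base, 1, 400))
  aln2 <- align_spacers(short)
  expect_equal(attr(aln2, "dropped"), "d")
  expect_error(align_spacers(c(a = base, d = substr(base, 1, 100))),
               "fewer than 2")
})

test_that("center-star cost is within the classical bound of optimal", {
  set.seed(2)
  # three short sequences, one with an indel
  s1 <- "ACGTACGTAA"
  s2 <- "ACGTACGTAA"
  s3 <- "ACGTCGTAA" # one deletion
  aln <- align_spacers(c(a = s1, b = s2, c = s3), min_length_fraction = 0.5)
  expect_true(length(unique(Biostrings::width(aln))) == 1L)
  # ungapping returns the inputs
  ungap <- gsub("-", "", as.character(aln))
  expect_identical(unname(ungap), c(s1, s2, s3))
  opt <- oracle_three_way_cost(s1, s2, s3)
  got <- msa_sp_cost(aln)
  # center-star is within 2(1 - 1/k) = 4/3 of the optimal SP cost
  expect_lte(got, ceiling(4 / 3 * opt))
})

test_that("JC69 distances behave and saturate loudly", {
  set.seed(3)
  s <- random_dna(1000)
  aln <- c(a = s, b = s, c = mutate_seq(s, 0.05))
  d <- as.matrix(stcap:::jc69_dist(aln))
  expect_equal(d["a", "a"], 0)
  expect_equal(d["a", "b"], 0)
  expect_equal(d, t(d))
  # JC correction exceeds the raw p-distance
  draw <- as.matrix(stcap:::jc69_dist(aln, model = "raw"))
  expect_gt(d["a", "c"], draw["a", "c"])
  sat <- c(a = strrep("A", 100), b = strrep("C", 100), c = strrep("G", 100))
  expect_error(stcap:::jc69_dist(sat), "saturated.*a / b")
})

test_that("NJ recovers additive four-taxon trees and 3-taxon closed form", {
  # additive matrix for ((A,B),(C,D)): verify via the four-point condition
  dm <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  dm["A", "B"] <- dm["B", "A"] <- 0.06   # 0.02 + 0.04
  dm["A", "C"] <- dm["C", "A"] <- 0.13   # 0.02 + 0.05 + 0.06
  dm["A", "D"] <- dm["D", "A"] <- 0.10   # 0.02 + 0.05 + 0.03
  dm["B", "C"] <- dm["C", "B"] <- 0.15
  dm["B", "D"] <- dm["D", "B"] <- 0.12
  dm["C", "D"] <- dm["D", "C"] <- 0.09   # 0.06 + 0.03
  sums <- c(AB_CD = dm["A", "B"] + dm["C", "D"],
            AC_BD = dm["A", "C"] + dm["B", "D"],
            AD_BC = dm["A", "D"] + dm["B", "C"])
  # four-point condition: the two larger sums are equal; smallest names
  # the true split
  expect_equal(sums[["AC_BD"]], sums[["AD_BC"]])
  expect_lt(sums[["AB_CD"]], sums[["AC_BD"]])
  tr <- ape::nj(stats::as.dist(dm))
  expect_equal(oracle_rf(tr, ape::read.tree(text = "((A,B),(C,D));")), 0)

  # 3 taxa: unique topology, branch lengths solve the three-point equations
  d3 <- matrix(0, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  d3["x", "y"] <- d3["y", "x"] <- 0.10
  d3["x", "z"] <- d3["z", "x"] <- 0.16
  d3["y", "z"] <- d3["z", "y"] <- 0.12
  t3 <- ape::nj(stats::as.dist(d3))
  bl <- stats::setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(unname(bl["x"]), (0.10 + 0.16 - 0.12) / 2)
  expect_equal(unname(bl["y"]), (0.10 + 0.12 - 0.16) / 2)
  expect_equal(unname(bl["z"]), (0.16 + 0.12 - 0.10) / 2)
})

test_that("nj_tree clamps negative branches and reports bootstrap support", {
  cs <- clock_species_tree()
  set.seed(11)
  seqs <- stcap:::evolve_tree_seqs(cs$tree, random_dna(3000))
  tr <- nj_tree(seqs, n_boot = 100L, seed = 2L)
  expect_true(all(tr$edge.length >= 0))
  sup <- suppressWarnings(as.integer(tr$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  # strong clades in a clean clock simulation get strong support
  expect_gt(mean(sup), 60)
  expect_equal(oracle_rf(tr, cs$tree), 0)
})

test_that("NJ on ultrametric distances matches UPGMA topology", {
  set.seed(13)
  for (rep in 1:10) {
    tr <- ape::rcoal(6)
    dm <- ape::cophenetic.phylo(tr)
    labs <- rownames(dm)
    nj_t <- ape::nj(stats::as.dist(dm))
    up <- ape::as.phylo(stats::hclust(stats::as.dist(dm), method = "average"))
    expect_equal(oracle_rf(nj_t, up), 0)
  }
})

test_that("strict-clock calibration recovers rates and ages", {
  # single calibration point: closed-form rate
  nwk <- "((a:0.05,b:0.05):0.036,c:0.086);"
  tr <- ape::read.tree(text = nwk)
  cal <- data.frame(tip_a = "a", tip_b = "c", age_mya = 8.6)
  ct <- calibrate(tr, cal)
  expect_equal(ct$rate, 0.01, tolerance = 1e-9)
  ages <- ct$ages
  ab <- ages$age_mya[vapply(ages$node, function(nd)
    clade_key(ct$tree, nd), character(1)) == "a|b"]
  expect_equal(ab, 5.0, tolerance = 1e-9)

  # the packaged calibration ages are the ape divergence set
  expect_setequal(divergence_calibrations()$age_mya, c(6.4, 8.6, 15.2, 19.5))

  # missing calibration tip errors informatively
  expect_error(calibrate(tr, data.frame(tip_a = "a", tip_b = "zz",
                                        age_mya = 1)), "zz")

  # simulated clock tree: >= 90% of node ages within 10%, over 3 seeds
  cs <- clock_species_tree()
  truth <- true_node_ages(cs$tree, cs$rate)
  fracs <- sapply(1:3, function(sd) {
    set.seed(sd)
    seqs <- stcap:::evolve_tree_seqs(cs$tree, random_dna(20000))
    njt <- nj_tree(seqs, n_boot = 0L)
    ct2 <- calibrate(njt, cs$calibrations, aln = seqs, n_boot_ci = 30L,
                     seed = sd)
    keys <- vapply(ct2$ages$node, function(nd) clade_key(ct2$tree, nd),
                   character(1))
    rel <- abs(ct2$ages$age_mya - truth[keys]) / truth[keys]
    # CI sanity: bounds bracket the estimate
    ok_ci <- !is.na(ct2$ages$ci_lo)
    expect_true(all(ct2$ages$ci_lo[ok_ci] <= ct2$ages$age_mya[ok_ci] + 1e-9))
    mean(rel[!is.na(rel)] <= 0.10)
  })
  expect_gte(mean(fracs), 0.9)

  # ages decrease from root to tips
  set.seed(4)
  seqs <- stcap:::evolve_tree_seqs(cs$tree, random_dna(5000))
  ct3 <- calibrate(nj_tree(seqs, n_boot = 0L), cs$calibrations)
  tr3 <- ct3$tree
  age_of <- stats::setNames(ct3$ages$age_mya, ct3$ages$node)
  n_tip <- length(tr3$tip.label)
  for (e in seq_len(nrow(tr3$edge))) {
    par <- tr3$edge[e, 1]; child <- tr3$edge[e, 2]
    if (child > n_tip) {
      expect_gte(age_of[[as.character(par)]] + 1e-9,
                 age_of[[as.character(child)]])
    }
  }
})
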