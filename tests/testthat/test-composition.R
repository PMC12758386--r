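test_that("build_matrix normalizes and applies both filters strictly", {
  u1 <- data.frame(arm = "a1", signature = c(rep("s1", 60), rep("s2", 40)))
  m <- build_matrix(u1, min_count = 0L, min_units = 1L)
  expect_equal(unname(m["a1", c("s1", "s2")]), c(0.6, 0.4))

  # arm with 1999 units is excluded at min_units = 2000
  u2 <- rbind(
    data.frame(arm = "big", signature = rep(c("s1", "s2"), 1000)),
    data.frame(arm = "small", signature = rep(c("s1", "s2"), length.out = 1999))
  )
  m2 <- build_matrix(u2, min_count = 0L, min_units = 2000L)
  expect_equal(rownames(m2), "big")

  # min_count is a strict >: a signature seen exactly 100 times drops,
  # 101 times survives
  u3 <- data.frame(arm = "a1", signature = c(rep("s100", 100), rep("s101", 101),
                                             rep("s500", 500)))
  m3 <- build_matrix(u3, min_count = 100L, min_units = 1L)
  expect_setequal(colnames(m3), c("s101", "s500"))
  # normalization uses the arm total before column filtering
  expect_equal(unname(m3["a1", "s101"]), 101 / 701)
  expect_error(build_matrix(u1, min_count = 1000L, min_units = 1L), "min_count")
  expect_error(build_matrix(u1, min_count = 0L, min_units = 10000L), "min_units")
})

test_that("cluster_arms: correlation distance oracle, support, invariance", {
  set.seed(42)
  base <- matrix(runif(5 * 10), 5, 10,
                 dimnames = list(paste0("arm", 1:5), paste0("v", 1:10)))
  base <- base / rowSums(base)
  d_pkg <- as.matrix(stats::as.dist(1 - stats::cor(t(base))))
  # direct recomputation oracle
  for (i in 1:4) for (j in (i + 1):5) {
    r <- sum((base[i, ] - mean(base[i, ])) * (base[j, ] - mean(base[j, ]))) /
      ((10 - 1) * stats::sd(base[i, ]) * stats::sd(base[j, ]))
    expect_equal(d_pkg[i, j], 1 - r, tolerance = 1e-12)
  }

  # duplicated-profile pair merges first with full support
  m <- rbind(twin1 = base[1, ], twin2 = base[1, ] + 1e-6 * runif(10),
             base[2:4, ])
  cl <- cluster_arms(m, n_boot = 50L, seed = 1L)
  merge1 <- cl$hclust$merge[1, ]
  expect_setequal(cl$hclust$labels[-merge1], c("twin1", "twin2"))
  twin_node <- ape::getMRCA(cl$phylo, c("twin1", "twin2"))
  lab <- cl$phylo$node.label[twin_node - ape::Ntip(cl$phylo)]
  expect_equal(as.integer(lab), 100L)

  # permuting row order leaves the bipartition set unchanged
  cl2 <- cluster_arms(m[sample(nrow(m)), ], n_boot = 10L, seed = 1L)
  expect_setequal(oracle_bipartitions(cl$phylo), oracle_bipartitions(cl2$phylo))

  # constant row is an explicit error naming the arm
  bad <- rbind(m, flatarm = rep(0.1, 10))
  expect_error(cluster_arms(bad), "flatarm")
  expect_error(cluster_arms(m[1:2, ]), "at least 3")
})

test_that("silhouette agrees with a brute-force implementation", {
  set.seed(7)
  x <- rbind(matrix(rnorm(60, 0), 20), matrix(rnorm(60, 4), 20),
             matrix(rnorm(60, 8), 20))
  cl <- stats::kmeans(x, 3, nstart = 5)$cluster
  d <- stats::dist(x)
  s_pkg <- cluster::silhouette(cl, d)
  s_ora <- oracle_silhouette(cl, d)
  expect_equal(unname(s_pkg[, "sil_width"]), s_ora, tolerance = 1e-12)
})

test_that("two-step k-means recovers planted variant groups and block types", {
  cfg <- sim_config(seed = 101L, n_arms = 6L, flank_length = 6000L,
                    boundary = list(width = 2000L))
  sim <- simulate_cap_genome(cfg)
  u <- sim$truth$units
  mat <- build_matrix(u, min_count = 10L, min_units = 100L)
  bt <- two_step_kmeans(mat, u, sim$truth$arrays, block_width = 2000L,
                        k_range = c(2L, 6L), seed = 3L)
  # the 8 default variants form 4 planted pairs
  expect_equal(bt$k1, 4L)
  expect_equal(bt$k2, 4L)
  # block composition rows sum to 1
  expect_true(all(abs(rowSums(bt$block_composition) - 1) < 1e-9))
  lab <- truth_block_labels(bt$blocks, sim$truth$blocks)
  ari <- mclust::adjustedRandIndex(lab, bt$blocks$type)
  expect_gte(ari, 0.9)
  # variant pairs cluster together in step 1: ARI vs planted pairing = 1
  sigs <- names(bt$variant_clusters)
  sigs[sigs == "<consensus>"] <- ""
  planted_group <- ceiling(match(sigs, cfg$variants) / 2)
  expect_equal(mclust::adjustedRandIndex(bt$variant_clusters, planted_group), 1)
})

test_that("two-step k-means rejects degenerate inputs", {
  u <- data.frame(arm = "a1", start = 0:9 * 32L, end = 1:10 * 32L,
                  signature = "s1")
  m <- matrix(c(0.5, 0.5), 1, 2, dimnames = list("a1", c("s1", "s2")))
  expect_error(
    two_step_kmeans(m, u, data.frame(arm = "a1", start = 0L, end = 320L),
                    block_width = 64L, k_range = c(2L, 3L)),
    "fewer variants"
  )
  m2 <- matrix(0.25, 2, 4, dimnames = list(c("a1", "a2"), paste0("s", 1:4)))
  expect_error(
    two_step_kmeans(m2, u, data.frame(arm = "a1", start = 0L, end = 320L),
                    block_width = 64L, k_range = c(2L, 3L)),
    "identical|undefined"
  )
})

test_that("partial terminal blocks merge into their neighbor", {
  spans <- data.frame(arm = "a", start = 0L, end = 4900L)
  b <- stcap:::tile_blocks(spans, 2000L)
  # 900 < half of 2000 -> merged: blocks are [0,2000) and [2000,4900)
  expect_equal(nrow(b), 2L)
  expect_equal(b$end[2], 4900L)
  b2 <- stcap:::tile_blocks(data.frame(arm = "a", start = 0L, end = 5100L), 2000L)
  expect_equal(nrow(b2), 3L) # 1100 >= half width stands alone
})
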