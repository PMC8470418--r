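test_that("jaccard distance matches hand-computed values and edge cases", {
  expect_equal(jaccard_distance(c(1, 1, 0, 0), c(1, 0, 1, 0)), 1 - 1 / 3)
  expect_equal(jaccard_distance(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(jaccard_distance(c(1, 1, 0, 0), c(0, 0, 1, 1)), 1)
  expect_error(jaccard_distance(c(0, 0), c(0, 0)), "all-zero")
  expect_error(jaccard_distance(c(1, 0), c(1, 0, 1)), "equal length")
})

test_that("jaccard distance is a metric on random nonzero 0/1 vectors", {
  set.seed(11)
  for (r in 1:200) {
    len <- sample(3:12, 1)
    v <- replicate(3, {
      x <- rbinom(len, 1, 0.5)
      if (all(x == 0)) x[sample(len, 1)] <- 1L
      x
    })
    a <- v[, 1]; b <- v[, 2]; c <- v[, 3]
    dab <- jaccard_distance(a, b)
    dba <- jaccard_distance(b, a)
    expect_identical(dab, dba)
    expect_gte(dab, 0); expect_lte(dab, 1)
    if (identical(a, b)) expect_identical(dab, 0)
    # triangle inequality
    expect_lte(dab, jaccard_distance(a, c) + jaccard_distance(c, b) + 1e-12)
  }
})

test_that("binary profile distances agree with the per-pair definition", {
  set.seed(3)
  m <- matrix(rbinom(40, 1, 0.5), 8, 5)
  m[rowSums(m) == 0, 1] <- 1L
  rownames(m) <- letters[1:8]
  dm <- as.matrix(binary_profile_dist(m))
  for (i in 1:7) for (j in (i + 1):8) {
    expect_equal(dm[i, j], jaccard_distance(m[i, ], m[j, ]))
  }
})

test_that("ward linkage reproduces simple configurations", {
  # two points merge at their distance
  d <- stats::as.dist(matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"), c("a", "b"))))
  hc <- ward_linkage(d)
  expect_equal(hc$height, 3)
  # duplicated points merge first at height 0
  dm <- as.matrix(stats::dist(rbind(a = c(0, 0), b = c(0, 0), c = c(3, 4))))
  hc <- ward_linkage(stats::as.dist(dm))
  expect_equal(hc$height[1], 0)
  expect_setequal(hclust_steps(hc)[[1]]$members, c("a", "b"))
  expect_error(ward_linkage(matrix(c(0, NA, NA, 0), 2)), "non-finite")
})

test_that("ward linkage agrees with stats::hclust ward.D2 partitions", {
  set.seed(21)
  for (r in 1:25) {
    n <- sample(5:12, 1)
    x <- matrix(rnorm(n * 3), n)
    rownames(x) <- sprintf("i%02d", seq_len(n))
    d <- stats::dist(x)
    a <- ward_linkage(d)
    b <- stats::hclust(d, method = "ward.D2")
    expect_equal(sort(a$height), sort(b$height), tolerance = 1e-9)
    for (k in 2:(n - 1)) {
      expect_equal(ari(stats::cutree(a, k), stats::cutree(b, k)), 1)
    }
  }
})

test_that("dynamic hybrid cut separates two planted blocks exactly", {
  m <- two_block_matrix()
  d <- binary_profile_dist(m)
  cl <- dynamic_hybrid_cut(ward_linkage(d), d, deep_split = 2, min_cluster_size = 5)
  expect_equal(max(cl), 2L)
  expect_equal(unname(ari(cl, rep(1:2, each = 10))), 1)
})

test_that("dynamic hybrid cut never returns clusters below min_cluster_size", {
  set.seed(5)
  for (r in 1:20) {
    n <- sample(8:30, 1)
    mcs <- sample(2:6, 1)
    x <- matrix(rnorm(n * 4), n)
    rownames(x) <- sprintf("i%02d", seq_len(n))
    d <- stats::dist(x)
    cl <- dynamic_hybrid_cut(ward_linkage(d), d, deep_split = sample(0:4, 1),
                             min_cluster_size = mcs)
    sizes <- table(cl[cl != 0])
    if (length(sizes)) expect_true(all(sizes >= mcs))
    expect_length(cl, n)
  }
})

test_that("equidistant items below twice the minimum size give one cluster or none", {
  n <- 7L
  dm <- matrix(1, n, n, dimnames = list(letters[1:n], letters[1:n]))
  diag(dm) <- 0
  d <- stats::as.dist(dm)
  cl <- dynamic_hybrid_cut(ward_linkage(d), d, deep_split = 2, min_cluster_size = 4)
  expect_lte(max(cl), 1L)
  sizes <- table(cl[cl != 0])
  if (length(sizes)) expect_true(all(sizes >= 4))
})

test_that("cluster labels are invariant under input row permutation", {
  set.seed(13)
  cfg <- simulation_config(seed = 13, n_genes = 150L,
                           module_specs = list(
                             list(size = 40L, active = 1:3, activation_prob = 1),
                             list(size = 40L, active = 5:8, activation_prob = 1)
                           ))
  de <- simulate_de_experiments(cfg)
  m <- build_binary_matrix(lapply(de$tables, filter_overexpressed))
  d1 <- binary_profile_dist(m)
  cl1 <- dynamic_hybrid_cut(ward_linkage(d1), d1, 2, 10)
  perm <- sample(nrow(m))
  d2 <- binary_profile_dist(m[perm, ])
  cl2 <- dynamic_hybrid_cut(ward_linkage(d2), d2, 2, 10)
  expect_equal(unname(ari(cl1[rownames(m)], cl2[rownames(m)])), 1)
})

test_that("correlation distance matches hand-computed values", {
  expect_equal(correlation_distance(c(1, 1, 0, 0), c(1, 0, 1, 0)), 1)
  expect_equal(correlation_distance(c(1, 0, 1, 0), c(1, 0, 1, 0)), 0)
  expect_equal(correlation_distance(c(1, 0, 1, 0), c(0, 1, 0, 1)), 2)
  # constant profile: maximal-distance sentinel
  expect_equal(correlation_distance(c(1, 1, 1), c(1, 0, 1)), 2)
  expect_error(correlation_distance(c(1, 0), c(1, 0, 1)), "equal length")
})

test_that("correlation distance matrix is symmetric, bounded, zero on equal rows", {
  set.seed(31)
  m <- matrix(rbinom(60, 1, 0.5), 10, 6)
  m[1, ] <- m[2, ]             # equal pair
  m[3, ] <- 1L                 # constant row
  rownames(m) <- letters[1:10]
  dm <- as.matrix(correlation_profile_dist(m))
  expect_equal(dm, t(dm))
  expect_true(all(dm >= -1e-12 & dm <= 2 + 1e-12))
  if (stats::sd(m[1, ]) > 0) expect_equal(dm[1, 2], 0)
  expect_true(all(dm[3, -3] == 2))
})
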