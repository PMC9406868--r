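test_that("correlation distance matches hand-computed values", {
  m <- cbind(a = c(1, 2, 3), b = c(3, 2, 1), c = c(1, 3, 2), d = c(1, 2, 3))
  rownames(m) <- c("g1", "g2", "g3")
  d <- correlation_distance(m)
  expect_equal(d["a", "d"], 0)          # identical profiles
  expect_equal(d["a", "b"], 2)          # perfectly anti-correlated
  expect_equal(d["a", "c"], 0.5)        # r = 1/2 by hand
  expect_equal(d, t(d), tolerance = 1e-12)
  expect_equal(unname(diag(d)), rep(0, 4))

  flat <- m; flat[, 2] <- 7
  expect_error(correlation_distance(flat), "b")
})

test_that("average-linkage clustering solves the 3-point example and boundaries", {
  d <- matrix(c(0, 1, 5, 1, 0, 6, 5, 6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  lab <- hclust_average(d, 2)
  expect_equal(lab[["A"]], lab[["B"]])
  expect_false(lab[["A"]] == lab[["C"]])
  # merge height of {A,B} with C is the average (5+6)/2 = 5.5
  hc <- hclust(as.dist(d), method = "average")
  expect_equal(hc$height, c(1, 5.5))

  expect_equal(unname(hclust_average(d, 3)), 1:3)     # singletons
  expect_equal(unname(hclust_average(d, 1)), rep(1L, 3))
  expect_error(hclust_average(d, 4), "between 1")
})

test_that("average linkage reproduces a brute-force UPGMA oracle", {
  set.seed(101)
  for (rep in 1:20) {
    n <- 7
    d <- as.matrix(dist(matrix(rnorm(n * 3), n)))
    dimnames(d) <- list(paste0("s", 1:n), paste0("s", 1:n))
    for (k in c(2, 3, 4)) {
      mine <- hclust_average(d, k)
      oracle <- oracle_upgma_cut(d, k)
      expect_equal(adjusted_rand_index(mine, oracle), 1)
    }
  }
})

test_that("consensus matrix is exact on perfectly separable duplicate blocks", {
  m <- two_block_matrix(per_block = 6)
  # exact duplicates have zero-variance issues only if constant; they are not
  res <- build_consensus(m, k = 2, n_iter = 50, subsample_fraction = 0.8,
                         seed = 1)
  C <- res$consensus
  block <- rep(1:2, each = 6)
  for (i in 1:11) for (j in (i + 1):12) {
    if (res$indicator_counts[i, j] > 0) {
      expect_equal(C[i, j], as.numeric(block[i] == block[j]))
    }
  }
  expect_true(all(res$connectivity_counts <= res$indicator_counts))
  expect_equal(unname(diag(C)), rep(1, 12))
})

test_that("no subsampling means every pair is always co-sampled; seeds reproduce", {
  m <- toy_matrix(genes = 8, samples = 10)
  res <- build_consensus(m, k = 3, n_iter = 25, subsample_fraction = 1)
  expect_true(all(res$indicator_counts == 25))
  r1 <- build_consensus(m, k = 3, n_iter = 40, subsample_fraction = 0.7, seed = 5)
  r2 <- build_consensus(m, k = 3, n_iter = 40, subsample_fraction = 0.7, seed = 5)
  expect_identical(r1$consensus, r2$consensus)
  expect_error(build_consensus(m, k = 1), "k must be")
  expect_error(build_consensus(m, k = 2, n_iter = 0), "n_iter")
})

test_that("consensus CDF area and the relative delta-area rule", {
  # two 6-blocks: 36 of 66 off-diagonal pairs are 0, 30 are 1; the ECDF is
  # 36/66 on [0,1), so the area is exactly 36/66
  C <- diag(12)
  C[1:6, 1:6] <- 1; C[7:12, 7:12] <- 1
  expect_equal(consensus_cdf_area(C), 36 / 66, tolerance = 1e-12)

  sel <- choose_k(c(0.5, 0.7, 0.72))
  expect_equal(sel$deltas, c(0.5, 0.4, 0.72 / 0.7 - 1), tolerance = 1e-12)
  expect_equal(sel$chosen_k, 3L)
  # fallback: no k >= 3 clears the threshold
  expect_equal(choose_k(c(0.5, 0.55, 0.56))$chosen_k, 2L)
  expect_error(choose_k(0.5), "at least two")
  expect_error(choose_k(c(0.5, 0.7), k_values = c(3, 4)), "starting at 2")
})

test_that("subtype assignment recovers planted structure and renumbers by size", {
  m <- two_block_matrix(per_block = 5)
  res <- build_consensus(m, k = 2, n_iter = 60, subsample_fraction = 0.8,
                         seed = 2)
  lab <- assign_subtypes(res)
  truth <- rep(1:2, each = 5)
  expect_equal(adjusted_rand_index(lab, truth), 1)

  cohort <- simulate_cohort(sim_config(seed = 33))
  tum <- names(cohort$truth$subtype)
  sel <- m6a_regulators()
  res3 <- build_consensus(cohort$expression[sel, tum], k = 3, n_iter = 150,
                          subsample_fraction = 0.8, seed = 3)
  lab3 <- assign_subtypes(res3)
  expect_gte(adjusted_rand_index(lab3, cohort$truth$subtype), 0.9)
  # labels renumbered 1..k by decreasing size
  expect_equal(sort(unique(lab3)), 1:3)
  sizes <- as.vector(table(lab3))
  expect_true(all(diff(sizes) <= 0))
})

test_that("cluster recovery degrades with noise", {
  ari_at <- function(sigma) {
    cohort <- simulate_cohort(sim_config(gene_noise_sd = sigma, seed = 44,
                                         n_background_genes = 10))
    tum <- names(cohort$truth$subtype)
    res <- build_consensus(cohort$expression[m6a_regulators(), tum], k = 3,
                           n_iter = 100, seed = 4)
    adjusted_rand_index(assign_subtypes(res), cohort$truth$subtype)
  }
  a <- ari_at(0.5); b <- ari_at(1); c <- ari_at(2)
  expect_gte(a, b - 0.02)
  expect_gt(b, c)
})

test_that("doubling iterations leaves the consensus essentially unchanged", {
  cohort <- simulate_cohort(sim_config(seed = 55, n_background_genes = 10))
  tum <- names(cohort$truth$subtype)
  m <- cohort$expression[m6a_regulators(), tum]
  c1 <- build_consensus(m, 3, n_iter = 200, seed = 6)$consensus
  c2 <- build_consensus(m, 3, n_iter = 400, seed = 7)$consensus
  expect_lt(mean(abs(c1 - c2)), 0.01)
  expect_lt(quantile(abs(c1 - c2), 0.99), 0.05)
})

test_that("adjusted Rand index agrees with mclust and is permutation invariant", {
  skip_if_not_installed("mclust")
  set.seed(9)
  for (i in 1:20) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
    relab <- c(9, 2, 7, 5)[a]
    expect_equal(adjusted_rand_index(relab, b), adjusted_rand_index(a, b))
  }
  expect_equal(adjusted_rand_index(1:5, c(2, 3, 4, 5, 6)), 1)
})

test_that("silhouette matches its definition, oracle, and boundary cases", {
  m <- two_block_matrix(per_block = 4)
  d <- correlation_distance(m)
  lab <- rep(1:2, each = 4)
  expect_equal(unname(silhouette_widths(d, lab)), rep(1, 8))

  # equidistant sample: a = b gives s = 0
  d2 <- matrix(1, 4, 4) - diag(4)
  dimnames(d2) <- list(paste0("s", 1:4), paste0("s", 1:4))
  s <- silhouette_widths(d2, c(1, 1, 2, 2))
  expect_equal(unname(s), rep(0, 4))

  set.seed(12)
  for (i in 1:20) {
    n <- 8
    d3 <- as.matrix(dist(matrix(rnorm(n * 2), n)))
    dimnames(d3) <- list(paste0("s", 1:n), paste0("s", 1:n))
    lab3 <- sample(1:3, n, replace = TRUE)
    if (length(unique(lab3)) < 2) next
    expect_equal(unname(silhouette_widths(d3, lab3)),
                 oracle_silhouette(d3, lab3), tolerance = 1e-12)
  }
  expect_error(silhouette_widths(d2, rep(1, 4)), "2 clusters")
})

test_that("silhouette agrees with the cluster package on random instances", {
  skip_if_not_installed("cluster")
  set.seed(13)
  n <- 25
  d <- as.matrix(dist(matrix(rnorm(n * 3), n)))
  dimnames(d) <- list(paste0("s", 1:n), paste0("s", 1:n))
  lab <- sample(1:3, n, replace = TRUE)
  ref <- cluster::silhouette(lab, dmatrix = d)
  expect_equal(unname(silhouette_widths(d, lab)), unname(ref[, "sil_width"]),
               tolerance = 1e-12)
})
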