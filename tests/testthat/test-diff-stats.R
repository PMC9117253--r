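test_that("moderated statistic follows its defining formula", {
  m <- moderated_statistic(c(1, 2, 3), c(1, 2, 3), 0.1)
  expect_equal(m$difference, 0)
  expect_equal(m$t_s0, 0)
  # zero pooled variance: the statistic is difference / s0
  m2 <- moderated_statistic(c(12, 12, 12), c(10, 10, 10), 0.1)
  expect_equal(m2$difference, 2)
  expect_equal(m2$t_s0, 20)
  expect_error(moderated_statistic(numeric(0), c(1, 2)), ">= 2")
})

test_that("s0 = 0 reproduces the textbook Student statistic", {
  set.seed(10)
  for (i in 1:25) {
    x <- rnorm(4 + i %% 3, 25, 1)
    y <- rnorm(3 + i %% 4, 24, 1)
    m <- moderated_statistic(x, y, s0 = 0)
    tt <- t.test(x, y, var.equal = TRUE)
    expect_equal(m$t_s0, unname(tt$statistic), tolerance = 1e-12)
  }
})

test_that("exact 3v3 enumeration reproduces the hand-counted p", {
  v <- matrix(c(12, 12, 12, 10, 10, 10), 1, 6, byrow = TRUE)
  tab <- make_table(v, treatments = c("PR619", "DMSO"), reps = 3)
  res <- permutation_test(tab, "PR619", "DMSO", test_config())
  expect_true(attr(res, "exact"))
  expect_equal(attr(res, "n_permutations"), 20)
  expect_equal(res$p, 2 / 20)
  expect_equal(res$difference, 2)
})

test_that("enumeration agrees with an independent brute-force oracle", {
  set.seed(77)
  for (i in 1:100) {
    x <- rnorm(3, 25 + (i %% 3), 1)
    y <- rnorm(3, 25, 1)
    tab <- make_table(matrix(c(x, y), 1, 6), treatments = c("T", "C"),
                      reps = 3)
    res <- permutation_test(tab, "T", "C", test_config(s0 = 0.1))
    expect_equal(res$p, oracle_perm_p(x, y, s0 = 0.1))
  }
})

test_that("right-sided testing counts only the upper tail", {
  set.seed(5)
  x <- rnorm(4, 27, 0.3)
  y <- rnorm(4, 25, 0.3)
  tab <- make_table(matrix(c(x, y), 1, 8), treatments = c("T", "C"),
                    reps = 4)
  res <- permutation_test(tab, "T", "C",
                          test_config(sidedness = "right_sided"))
  expect_equal(res$p, oracle_perm_p(x, y, s0 = 0.1, two_sided = FALSE))
  res_flip <- permutation_test(tab, "C", "T",
                               test_config(sidedness = "right_sided"))
  expect_gt(res_flip$p, 0.5)
})

test_that("all-null data keeps the q <= 0.05 fraction at the nominal level", {
  d <- study_design(c("DMSO", "PR619"), replicates = 5)
  sim <- simulate_site_table(d, 2000, effect_fractions = c(null = 1),
                             noise_sd = 0.25, seed = 17,
                             missing_location = 0)  # no censoring
  res <- permutation_test(sim$table, "PR619", "DMSO",
                          test_config(seed = 17))
  mc_se <- sqrt(0.05 * 0.95 / 2000)
  expect_lte(mean(res$q <= 0.05), 0.05 + 3 * mc_se)
})

test_that("planted effects are detected with high sensitivity and unbiased size", {
  d <- study_design(c("DMSO", "PR619"), replicates = 5)
  sim <- simulate_site_table(
    d, 1000, effect_fractions = c(null = 0.8, enriched = 0.2),
    effect_size = 2, noise_sd = 0.25, seed = 23
  )
  tab <- filter_valid_values(sim$table, "ALL_IN_ANY_GROUP")
  tab <- impute_left_censored(tab, imputation_params(seed = 23))
  res <- permutation_test(tab, "PR619", "DMSO", test_config(seed = 23))
  truth <- sim$truth[match(res$entry_id, sim$truth$entry_id), ]
  enr <- truth$class == "enriched"
  expect_gte(mean(res$significant[enr]), 0.90)
  expect_lt(abs(mean(res$difference[enr]) - 2), 0.1)
})

test_that("q-values are invariant to input row order", {
  set.seed(31)
  d <- study_design(c("DMSO", "MG132"), replicates = 4)
  sim <- simulate_site_table(d, 60, seed = 31, missing_location = 0)
  tab <- sim$table
  res <- permutation_test(tab, "MG132", "DMSO", test_config(seed = 2))
  perm <- sample(n_entries(tab))
  res2 <- permutation_test(subset_table(tab, perm), "MG132", "DMSO",
                           test_config(seed = 2))
  expect_equal(res2$q[match(res$entry_id, res2$entry_id)], res$q)
})

test_that("q is monotone along the ranked statistics", {
  d <- study_design(c("DMSO", "PR619"), replicates = 4)
  sim <- simulate_site_table(d, 200, seed = 3, missing_location = 0)
  res <- permutation_test(sim$table, "PR619", "DMSO", test_config(seed = 3))
  ord <- order(-abs(res$t_s0), res$entry_id)
  expect_true(all(diff(res$q[ord]) >= -1e-12))
  expect_true(all(res$q >= 0 & res$q <= 1))
  expect_identical(res$significant, res$q <= 0.05)
})

test_that("the parental gate matches a one-sided t-test oracle and shrinks with alpha", {
  set.seed(9)
  n <- 20
  X <- matrix(rnorm(n * 3, 25 + rep(c(0, 2), each = n / 2 * 3)), n, 3)
  Y <- matrix(rnorm(n * 3, 25), n, 3)
  his10 <- make_table(X, treatments = "HIS", reps = 3, level = "protein")
  parental <- make_table(Y, treatments = "PAR", reps = 3, level = "protein")
  gate <- his10_substrate_gate(his10, parental, alpha = 0.05)
  oracle <- vapply(seq_len(n), function(i) {
    t.test(X[i, ], Y[i, ], var.equal = TRUE,
           alternative = "greater")$p.value
  }, numeric(1))
  expect_identical(sort(gate), sort(his10$entries$entry_id[oracle < 0.05]))
  g01 <- his10_substrate_gate(his10, parental, alpha = 0.01)
  g10 <- his10_substrate_gate(his10, parental, alpha = 0.10)
  expect_true(all(g01 %in% gate))
  expect_true(all(gate %in% g10))
})

test_that("pearson validates its input and matches hand arithmetic", {
  expect_equal(pearson(1:5, 2 * (1:5) + 1), 1)
  expect_equal(pearson(1:5, -(1:5)), -1)
  expect_equal(pearson(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(pearson(1:3, 1:4), "equal length")
  expect_error(pearson(c(1, 1, 1), 1:3), "constant")
})

test_that("pca_project explains rank-one structure and orders variance", {
  base <- rnorm(10)
  v <- outer(base, c(1, 2, 3, 4, 5, 6)) +
    matrix(rnorm(60, 0, 1e-4), 10, 6)
  tab <- make_table(v)
  pc <- pca_project(tab, 2)
  expect_gte(pc$explained_variance[1], 0.999)
  expect_true(all(diff(pc$explained_variance) <= 0))
  expect_error(pca_project(tab, 10), "rank")
})

test_that("samples of a treatment cluster together in PC space", {
  set.seed(41)
  trt_effect <- list(DMSO = rep(0, 300),
                     MG132 = rnorm(300, 0, 1.5),
                     PR619 = rnorm(300, 0, 1.5))
  v <- do.call(cbind, lapply(rep(names(trt_effect), each = 5), function(g) {
    25 + trt_effect[[g]] + rnorm(300, 0, 0.25)
  }))
  tab <- make_table(v, treatments = names(trt_effect), reps = 5)
  pc <- pca_project(tab, 2)
  co <- pc$coordinates
  trt <- tab$samples$treatment
  for (i in seq_len(nrow(co))) {
    dists <- sqrt(rowSums((co - matrix(co[i, ], nrow(co), 2,
                                       byrow = TRUE))^2))
    nn <- order(dists)[2]
    expect_identical(trt[nn], trt[i])
  }
})

test_that("cluster_heatmap keeps planted blocks contiguous", {
  set.seed(6)
  pattern <- rep(c(3, -3), each = 3)
  block1 <- matrix(rep(pattern, each = 25), 25, 6) +
    matrix(rnorm(150, 0, 0.2), 25, 6)
  block2 <- matrix(rep(-pattern, each = 25), 25, 6) +
    matrix(rnorm(150, 0, 0.2), 25, 6)
  v <- rbind(block1, block2)[sample(50), ]
  is_b1 <- v[, 1] > 0
  tab <- center_rows(make_table(v))
  ch <- cluster_heatmap(tab, k = 4, iterations = 100, seed = 2)
  ord_membership <- is_b1[ch$order]
  expect_equal(sum(abs(diff(ord_membership))), 1)
})

test_that("k equal to the row count degenerates to plain hierarchical clustering", {
  set.seed(8)
  v <- matrix(rnorm(48, 0, 1), 8, 6)
  tab <- make_table(v)
  ch <- cluster_heatmap(tab, k = 8, seed = 1)
  expect_identical(sort(ch$clusters), 1:8)
  plain <- hclust(dist(v), method = "average")$order
  expect_identical(ch$order, as.integer(plain))
  expect_error(cluster_heatmap(tab, k = 9), "exceeds")
})
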