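test_that("z-scoring standardizes with sample sd and is idempotent", {
  expect_equal(zscore_map(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(1)
  z <- zscore_map(rnorm(100, 5, 3))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(zscore_map(z), z, tolerance = 1e-12)
  expect_error(zscore_map(rep(2, 10)), class = "picafuse_domain_error")
  expect_error(zscore_map(1), class = "picafuse_domain_error")
})

test_that("thresholding is strict and counts survivors", {
  out <- threshold_map(c(3.0, 1.0, -2.6), cutoff = 2.5)
  expect_equal(out$mask, c(TRUE, FALSE, TRUE))
  expect_equal(out$n_voxels, 2L)
  expect_equal(threshold_map(c(2.5), 2.5)$n_voxels, 0L)  # boundary excluded
  expect_equal(threshold_map(rep(0, 5), 2.5)$n_voxels, 0L)
  # invariance to affine rescaling of the underlying map
  set.seed(2)
  s <- rnorm(500)
  m1 <- threshold_map(zscore_map(s), 2.5)$mask
  m2 <- threshold_map(zscore_map(7 * s - 3), 2.5)$mask
  expect_identical(m1, m2)
})

test_that("loading group tests match closed forms", {
  # identical groups: t = 0, p = 1
  A <- cbind(rep(c(1, 2, 3, 4), 2))
  labels <- rep(c("a", "b"), each = 4)
  out <- loading_group_test(A, labels)
  expect_equal(out$t, 0)
  expect_equal(out$p, 1)
  # strong separation: p below 1e-10
  set.seed(3)
  A2 <- cbind(c(rnorm(50, 0, 0.1), rnorm(50, 1, 0.1)))
  out2 <- loading_group_test(A2, rep(c("g1", "g2"), each = 50))
  expect_lt(out2$p, 1e-10)
  # agreement with stats::t.test as the oracle
  A3 <- cbind(rnorm(20), rnorm(20))
  lab3 <- rep(c("x", "y"), 10)
  out3 <- loading_group_test(A3, lab3)
  ref <- t.test(A3[lab3 == "x", 2], A3[lab3 == "y", 2])
  expect_equal(out3$t[2], unname(ref$statistic))
  expect_equal(out3$p[2], ref$p.value)
})

test_that("null loading tests are calibrated", {
  set.seed(4)
  n_comp <- 1000L
  A <- matrix(rnorm(40 * n_comp), 40, n_comp)
  labels <- rep(c("a", "b"), each = 20)
  out <- loading_group_test(A, labels)
  frac <- mean(out$p < 0.05)
  expect_gte(frac, 0.036)
  expect_lte(frac, 0.064)
})

test_that("voxel-wise tests agree with t.test and flag constant voxels", {
  set.seed(5)
  x <- matrix(rnorm(30 * 50), 30, 50)
  labels <- rep(c("a", "b"), each = 15)
  x[, 7] <- x[, 7] + ifelse(labels == "a", 2, 0)   # injected shift
  x[, 9] <- 1                                        # constant voxel
  expect_message(out <- voxelwise_group_test(x, labels), "1 zero-variance")
  ref <- t.test(x[labels == "a", 7], x[labels == "b", 7])
  expect_equal(out$t[7], unname(ref$statistic), tolerance = 1e-12)
  expect_equal(out$p[7], ref$p.value, tolerance = 1e-12)
  expect_true(is.na(out$t[9]))
  expect_lt(out$p[7], 1e-4)
})

test_that("an injected shift of d = 2 at n = 140 is overwhelming", {
  set.seed(6)
  x <- matrix(rnorm(140 * 10), 140, 10)
  labels <- rep(c("MCI", "NC"), c(65, 75))
  x[, 3] <- x[, 3] + ifelse(labels == "MCI", 2, 0)
  out <- voxelwise_group_test(x, labels)
  expect_lt(out$p[3], 1e-6)
})

test_that("permuted labels give a null-consistent maximum |t|", {
  set.seed(7)
  x <- matrix(rnorm(40 * 80), 40, 80)
  labels <- sample(rep(c("a", "b"), each = 20))
  obs_max <- max(abs(voxelwise_group_test(x, labels)$t))
  perm_max <- vapply(1:200, function(i) {
    max(abs(voxelwise_group_test(x, sample(labels))$t))
  }, numeric(1))
  p_of_max <- mean(perm_max >= obs_max)
  expect_gt(p_of_max, 0.025)  # observed max not an outlier under the null
})

test_that("cross-modal correlations carry valid p/q structure", {
  set.seed(8)
  A1 <- matrix(rnorm(140 * 8), 140, 8)
  A2 <- matrix(rnorm(140 * 8), 140, 8)
  out <- crossmodal_correlations(A1, A2)
  expect_equal(nrow(out), 64L)
  expect_true(all(out$q >= out$p))
  expect_true(all(abs(out$r) <= 1))
  # self-correlation r = 1
  self <- crossmodal_correlations(A1[, 1, drop = FALSE], A1[, 1, drop = FALSE])
  expect_equal(self$r, 1)
  # p matches cor.test
  ct <- cor.test(A1[, 2], A2[, 3])
  expect_equal(out$p[out$i == 2 & out$j == 3], ct$p.value, tolerance = 1e-12)
  expect_error(crossmodal_correlations(A1, A2[1:10, ]),
               class = "picafuse_domain_error")
})

test_that("BH FDR matches the exhaustive step-up oracle", {
  out <- bh_fdr(rep(0.01, 10), alpha = 0.05)
  expect_equal(out$q, rep(0.01, 10))
  expect_true(all(out$reject))
  p <- c(0.01, 0.02, 0.03, 0.5)
  expect_equal(bh_fdr(p, 0.05)$reject, bh_stepup_oracle(p, 0.05))
  set.seed(9)
  for (i in 1:25) {
    p <- runif(20)^sample(1:3, 1)
    expect_equal(bh_fdr(p, 0.05)$reject, bh_stepup_oracle(p, 0.05))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), class = "picafuse_domain_error")
  # BH rejections contain Bonferroni rejections
  set.seed(10)
  p <- runif(50)^2
  bh <- bh_fdr(p, 0.05)$reject
  bonf <- p < 0.05 / length(p)
  expect_true(all(bh[bonf]))
})

test_that("BH keeps the realized false discovery rate at its level", {
  set.seed(11)
  reps <- 300L
  m <- 64L
  fdr <- vapply(seq_len(reps), function(i) {
    p <- runif(m)                       # global null: any rejection is false
    rej <- bh_fdr(p, 0.05)$reject
    if (any(rej)) 1 else 0              # FDP is 0/1 under the global null
  }, numeric(1))
  realized <- mean(fdr) * 1             # E[FDP] estimate
  se <- sd(fdr) / sqrt(reps)
  expect_lte(realized, 0.05 + 2 * se)
})

test_that("covariate screening behaves at the null and at identity", {
  set.seed(12)
  n <- 80L
  A <- matrix(rnorm(n * 3), n, 3)
  age <- rnorm(n, 70, 6)
  sex <- sample(c("M", "F"), n, replace = TRUE)
  out <- covariate_check(A, age, sex)
  expect_equal(nrow(out), 3L)
  # loadings equal to age give r = 1
  out2 <- covariate_check(cbind(age), age, sex)
  expect_equal(out2$age_r, 1)
  # residualized loadings are orthogonal to age
  out3 <- covariate_check(A, age, sex, residualize = TRUE)
  resid <- attr(out3, "residualized")
  expect_lt(max(abs(cor(resid, age))), 1e-10)
  expect_error(covariate_check(A, rep(1, n), sex), class = "picafuse_domain_error")
})

test_that("null covariate associations have uniform p-values", {
  set.seed(13)
  ps <- unlist(lapply(1:100, function(i) {
    A <- matrix(rnorm(40), 40, 1)
    covariate_check(A, rnorm(40, 70, 5),
                    sample(c("M", "F"), 40, replace = TRUE))$age_p
  }))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})

test_that("summary-statistics Welch t reproduces the cognitive-score contrast", {
  out <- welch_t_summary(25.7, 2.3, 65, 27.9, 1.7, 75)
  expect_lt(out$p, 0.001)
  expect_lt(out$t, 0)
  # oracle: the same test from raw data with matching summaries
  x <- scale(rnorm(65)) * 2.3 + 25.7
  y <- scale(rnorm(75)) * 1.7 + 27.9
  ref <- t.test(x, y)
  got <- welch_t_summary(mean(x), sd(x), 65, mean(y), sd(y), 75)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
})

test_that("the cohort table runs the right test per variable", {
  set.seed(14)
  st <- tibble::tibble(
    subject_id = sprintf("S%03d", 1:140),
    group = rep(c("MCI", "NC"), c(65, 75)),
    age = rnorm(140, 75, 6),
    sex = sample(c("M", "F"), 140, replace = TRUE),
    apoe4 = rbinom(140, 1, 0.45),
    mmse = round(c(rnorm(65, 25.7, 2.3), rnorm(75, 27.9, 1.7))),
    cdr = rep(c(0.5, 0), c(65, 75))
  )
  out <- cohort_table(st)
  expect_setequal(out$variable, c("age", "mmse", "sex", "apoe4", "cdr"))
  expect_equal(out$test[out$variable == "sex"], "chi-square")
  expect_equal(out$test[out$variable == "cdr"], "Mann-Whitney")
  expect_lt(out$p[out$variable == "mmse"], 0.001)
  expect_lt(out$p[out$variable == "cdr"], 0.001)
  expect_true(all(out$p >= 0 & out$p <= 1))
  expect_error(cohort_table(st[, -2]), class = "picafuse_domain_error")
})

test_that("identical groups give null statistics across all tests", {
  # exactly mirrored groups
  vals <- rnorm(20, 70, 5)
  st <- tibble::tibble(
    subject_id = sprintf("S%02d", 1:40),
    group = rep(c("A", "B"), each = 20),
    age = rep(vals, 2),
    sex = rep(rep(c("M", "F"), 10), 2)
  )
  out <- cohort_table(st)
  expect_equal(out$statistic[out$variable == "age"], 0)
  expect_equal(out$p[out$variable == "age"], 1)
  expect_equal(out$statistic[out$variable == "sex"], 0)
  expect_equal(out$p[out$variable == "sex"], 1)
})

test_that("the 2x2 chi-square equals its closed form", {
  tab <- matrix(c(32, 33, 33, 42), 2, byrow = TRUE)
  a <- 32; b <- 33; c <- 33; d <- 42
  n <- a + b + c + d
  closed <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  got <- suppressWarnings(chisq.test(tab, correct = FALSE))
  expect_equal(unname(got$statistic), closed, tolerance = 1e-12)
  st <- tibble::tibble(
    subject_id = sprintf("S%03d", 1:n),
    group = rep(c("MCI", "NC"), c(a + b, c + d)),
    apoe4 = c(rep(1, a), rep(0, b), rep(1, c), rep(0, d))
  )
  out <- cohort_table(st)
  expect_equal(out$statistic[out$variable == "apoe4"], closed, tolerance = 1e-12)
})
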