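test_that("ROI features equal brute-force mask means", {
  set.seed(31)
  mask <- array(TRUE, c(4, 4, 4))
  values <- matrix(rnorm(5 * 64), 5, 64)
  vm <- voxel_matrix(values, mask, subject_ids = sprintf("s%d", 1:5))
  masks <- list(one = c(TRUE, rep(FALSE, 63)),
                some = rep(c(TRUE, FALSE), 32))
  ft <- extract_roi_features(vm, masks, condition = "Tau")
  # single-voxel mask: the feature is that voxel
  expect_equal(ft$one, values[, 1])
  # brute-force mean over enumerated voxels
  expect_equal(ft$some, apply(values[, which(masks$some)], 1, mean))
  expect_equal(attr(ft, "condition"), "Tau")
  # constant image: every mask feature is that constant
  vmc <- voxel_matrix(matrix(3, 2, 64), mask)
  ftc <- extract_roi_features(vmc, masks)
  expect_true(all(ftc$one == 3, ftc$some == 3))
  expect_error(extract_roi_features(vm, list(bad = rep(FALSE, 64))),
               "bad", class = "picafuse_domain_error")
})

test_that("stratified folds partition 65/75 into 13+15 per fold", {
  labels <- rep(c("MCI", "NC"), c(65, 75))
  folds <- stratified_kfold(labels, k = 5L, seed = 1L)
  expect_equal(unname(table(folds)), rep(28L, 5), ignore_attr = TRUE)
  tab <- table(folds, labels)
  expect_true(all(tab[, "MCI"] == 13L))
  expect_true(all(tab[, "NC"] == 15L))
  # partition: every subject in exactly one fold
  expect_equal(length(folds), 140L)
  expect_true(all(folds %in% 1:5))
  # deterministic given seed, different across seeds
  expect_identical(folds, stratified_kfold(labels, 5L, seed = 1L))
  expect_false(identical(folds, stratified_kfold(labels, 5L, seed = 2L)))
  expect_error(stratified_kfold(rep(c("a", "b"), c(3, 50)), k = 5L),
               class = "picafuse_domain_error")
})

test_that("uneven class sizes still balance folds within one subject", {
  labels <- rep(c("a", "b"), c(23, 31))
  folds <- stratified_kfold(labels, k = 5L, seed = 3L)
  sizes <- table(folds)
  expect_lte(max(sizes) - min(sizes), 1L)
  tab <- table(folds, labels)
  expect_lte(max(tab[, "a"]) - min(tab[, "a"]), 1L)
  expect_lte(max(tab[, "b"]) - min(tab[, "b"]), 1L)
})

test_that("AUC matches the brute-force concordant-pair count", {
  expect_equal(roc_auc(c(5, 4, 3, 1, 2), rep(c("pos", "neg"), c(2, 3)),
                       positive = "pos"), 1)
  expect_equal(roc_auc(rep(1, 10), rep(c("pos", "neg"), 5), positive = "pos"), 0.5)
  pair_oracle <- function(scores, pos) {
    sp <- scores[pos]
    sn <- scores[!pos]
    conc <- 0
    for (a in sp) for (b in sn) conc <- conc + (a > b) + 0.5 * (a == b)
    conc / (length(sp) * length(sn))
  }
  set.seed(32)
  for (i in 1:50) {
    n <- sample(6:20, 1)
    scores <- sample(1:8, n, replace = TRUE)  # ties likely
    labels <- sample(c("pos", "neg"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels, positive = "pos"),
                 pair_oracle(scores, labels == "pos"))
  }
  expect_error(roc_auc(1:5, rep("pos", 5)), class = "picafuse_domain_error")
})

test_that("AUC is invariant to monotone transforms and flips under negation", {
  set.seed(33)
  scores <- rnorm(40)
  labels <- sample(c("pos", "neg"), 40, replace = TRUE, prob = c(0.4, 0.6))
  a <- roc_auc(scores, labels, positive = "pos")
  expect_equal(roc_auc(exp(scores), labels, positive = "pos"), a)
  expect_equal(roc_auc(-scores, labels, positive = "pos"), 1 - a)
})

test_that("cross-validation is perfect on separable features", {
  set.seed(34)
  labels <- rep(c("MCI", "NC"), c(30, 30))
  ft <- tibble::tibble(subject_id = sprintf("s%d", 1:60),
                       f1 = ifelse(labels == "MCI", 5, -5) + rnorm(60, sd = 0.1),
                       f2 = rnorm(60))
  attr(ft, "condition") <- "Tau"
  rep <- cross_validate(ft, labels, k = 5L, seed = 1L)
  expect_equal(rep$mean$acc, 100)
  expect_equal(rep$mean$auc, 100)
  expect_equal(rep$mean$sen, 100)
  expect_equal(rep$mean$spe, 100)
  expect_equal(nrow(rep$folds), 5L)
  expect_equal(rep$mean$acc, mean(rep$folds$acc))
})

test_that("permuted labels give chance-level AUC", {
  set.seed(35)
  aucs <- vapply(1:30, function(i) {
    labels <- sample(rep(c("MCI", "NC"), c(65, 75)))
    ft <- tibble::tibble(subject_id = sprintf("s%d", 1:140),
                         f1 = rnorm(140), f2 = rnorm(140), f3 = rnorm(140))
    cross_validate(ft, labels, k = 5L, seed = i)$mean$auc
  }, numeric(1))
  expect_gt(mean(aucs), 40)
  expect_lt(mean(aucs), 60)
})

test_that("standardization and the model are fitted on training folds only", {
  # oracle: rebuild each fold's pipeline from the training rows alone; the
  # reported metrics must match exactly, and distorting the held-out rows
  # must leave that fold's fitted scorer (checked on clean probe rows)
  # unchanged.
  set.seed(36)
  labels <- rep(c("MCI", "NC"), c(20, 20))
  ft <- tibble::tibble(subject_id = sprintf("s%d", 1:40),
                       f1 = ifelse(labels == "MCI", 1, -1) + rnorm(40, sd = 0.8),
                       f2 = rnorm(40))
  rep <- cross_validate(ft, labels, k = 5L, seed = 7L)
  folds <- stratified_kfold(labels, k = 5L, seed = 7L)
  x <- as.matrix(ft[, c("f1", "f2")])
  for (f in 1:5) {
    tr <- folds != f
    scorer <- picafuse:::fit_linear_classifier(x[tr, ], labels[tr], "MCI")
    sc <- scorer(x[!tr, , drop = FALSE])
    truth <- labels[!tr] == "MCI"
    expect_equal(rep$folds$acc[f], 100 * mean((sc > 0) == truth))
    # the scorer is a pure function of the training rows: distorting the
    # held-out rows cannot change scores assigned to a clean probe
    x_bad <- x
    x_bad[!tr, ] <- x_bad[!tr, ] + 1e6
    scorer2 <- picafuse:::fit_linear_classifier(x_bad[tr, ], labels[tr], "MCI")
    probe <- x[1:2, , drop = FALSE]
    expect_identical(scorer(probe), scorer2(probe))
  }
})

test_that("single-class training folds are rejected", {
  labels <- rep(c("MCI", "NC"), c(10, 10))
  x <- matrix(rnorm(40), 20, 2)
  expect_error(
    picafuse:::fit_linear_classifier(x, rep("MCI", 20), "MCI"),
    class = "picafuse_degenerate_error"
  )
})

test_that("single-feature tables fall back to unpenalized logistic scoring", {
  set.seed(37)
  labels <- rep(c("MCI", "NC"), each = 20)
  ft <- tibble::tibble(subject_id = sprintf("s%d", 1:40),
                       f1 = ifelse(labels == "MCI", 2, -2) + rnorm(40, sd = 0.4))
  rep <- cross_validate(ft, labels, k = 5L, seed = 2L)
  expect_gt(rep$mean$acc, 90)
})

test_that("tidy and glance summarise reports on the percent scale", {
  set.seed(38)
  labels <- rep(c("MCI", "NC"), c(30, 30))
  ft <- tibble::tibble(subject_id = sprintf("s%d", 1:60),
                       f1 = rnorm(60) + (labels == "MCI"), f2 = rnorm(60))
  attr(ft, "condition") <- "All"
  rep <- cross_validate(ft, labels, k = 5L, seed = 1L)
  td <- tidy(rep)
  expect_equal(nrow(td), 5L)
  expect_true(all(td$acc >= 0 & td$acc <= 100))
  g <- glance(rep)
  expect_equal(g$condition, "All")
  expect_equal(g$acc, mean(td$acc))
  expect_s3_class(autoplot(rep), "ggplot")
})
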