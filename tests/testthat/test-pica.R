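test_that("whitening yields identity covariance and lossless reconstruction", {
  set.seed(1)
  x <- matrix(rnorm(10 * 400), 10, 400) * rep(sqrt(1:10), 400)
  wh <- whiten(x, k = 10L)
  covw <- tcrossprod(wh$xw) / (ncol(x) - 1)
  expect_equal(covw, diag(10), tolerance = 1e-8)
  # full-rank retention: dewhitening reconstructs the centred data
  recon <- wh$dewhitener %*% wh$xw + wh$row_means
  expect_lt(max(abs(recon - x)) / max(abs(x)), 1e-6)
})

test_that("retained variance equals the top-k eigenvalue fraction", {
  set.seed(2)
  x <- matrix(rnorm(12 * 300), 12, 300)
  wh <- whiten(x, k = 5L)
  xc <- x - rowMeans(x)
  ev <- eigen(tcrossprod(xc) / (ncol(x) - 1), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(wh$var_retained, sum(ev[1:5]) / sum(ev), tolerance = 1e-10)
})

test_that("whitening refuses k beyond the measured rank", {
  set.seed(3)
  low <- matrix(rnorm(8 * 3), 8, 3) %*% matrix(rnorm(3 * 200), 3, 200)
  err <- expect_error(whiten(low, k = 5L), class = "picafuse_rank_error")
  expect_match(conditionMessage(err), "rank 3")
})

test_that("the infomax step matches its closed forms", {
  W <- diag(3)
  # zero batch: g(0) = 1/2, so the update is eta * W
  zero_batch <- matrix(0, 3, 50)
  expect_equal(infomax_step(W, zero_batch, 0.1), W + 0.1 * W)
  # eta = 0 leaves W unchanged
  set.seed(4)
  batch <- matrix(rnorm(3 * 50), 3, 50)
  expect_equal(infomax_step(W, batch, 0), W)
})

test_that("the infomax gradient agrees with numerical differentiation", {
  set.seed(5)
  W <- diag(3) + 0.1 * matrix(rnorm(9), 3, 3)
  batch <- matrix(rnorm(3 * 200), 3, 200)
  # plain-gradient form: dJ/dW = (W^T)^-1 + mean (1-2y) x^T
  u <- W %*% batch
  y <- plogis(u)
  analytic <- t(solve(W)) + (1 - 2 * y) %*% t(batch) / ncol(batch)
  eps <- 1e-6
  numeric_grad <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    Wp <- W; Wp[i, j] <- Wp[i, j] + eps
    Wm <- W; Wm[i, j] <- Wm[i, j] - eps
    numeric_grad[i, j] <- (infomax_objective(Wp, batch) -
                             infomax_objective(Wm, batch)) / (2 * eps)
  }
  expect_lt(max(abs(numeric_grad - analytic)) / max(abs(analytic)), 1e-4)
  # and the natural-gradient step is that gradient right-multiplied by W^T W
  step <- infomax_step(W, batch, 1) - W
  expect_equal(step, analytic %*% crossprod(W), tolerance = 1e-8)
})

test_that("divergence is signalled and annealing recovers", {
  W <- matrix(1e9, 2, 2)
  batch <- matrix(rnorm(2 * 10), 2, 10)
  expect_error(infomax_step(W, batch, 10), class = "picafuse_divergence")
})

test_that("noise-free independent super-Gaussian sources are recovered almost exactly", {
  # idealized construction: independent Laplace sources, random mixing
  set.seed(9)
  k <- 4L; n <- 60L; v <- 1500L
  rlaplace <- function(m) {
    u <- runif(m) - 0.5
    -sign(u) * log(1 - 2 * abs(u)) / sqrt(2)
  }
  S1 <- matrix(rlaplace(k * v), k, v)
  S2 <- matrix(rlaplace(k * v), k, v)
  A1 <- matrix(rnorm(n * k), n, k)
  A2 <- matrix(rnorm(n * k), n, k)
  # unconstrained: this exercises the infomax core itself (at n = 60 a
  # chance cross-loading correlation can cross the activation threshold)
  fit <- parallel_ica(A1 %*% S1, A2 %*% S2,
                      quick_pica_config(seed = 9L, max_iterations = 4000L,
                                        lambda = 0))
  for (m in 1:2) {
    match <- match_components(fit, list(S1, S2)[[m]], m)
    expect_gte(min(match$matched_r), 0.99)
    expect_lt(match$amari, 0.05)
  }
})

test_that("blob-source recovery at default noise meets the recovery floor", {
  cfg <- small_sim_config(seed = 9L)
  ds <- synthesize_dataset(cfg)
  fit <- parallel_ica(ds[[1]], ds[[2]], quick_pica_config(seed = 9L))
  for (m in 1:2) {
    match <- match_components(fit, ds$truth$sources[[m]], m)
    expect_gte(match$mean_abs_r, 0.95)
    expect_lte(match$amari, 0.1)
  }
})

test_that("sources are standardized with nonnegative skewness and A*S reconstructs", {
  cfg <- small_sim_config(seed = 10L)
  ds <- synthesize_dataset(cfg)
  fit <- parallel_ica(ds[[1]], ds[[2]], quick_pica_config(seed = 10L))
  for (m in 1:2) {
    S <- fit$modalities[[m]]$sources
    A <- fit$modalities[[m]]$loadings
    expect_equal(rowMeans(S), rep(0, nrow(S)), tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(apply(S, 1, sd), rep(1, nrow(S)), tolerance = 1e-6,
                 ignore_attr = TRUE)
    skew <- apply(S, 1, function(s) mean((s - mean(s))^3) / sd(s)^3)
    expect_true(all(skew >= -1e-8))
    # A %*% S approximates the centred data up to PCA truncation + noise
    xc <- ds[[m]]$values - rowMeans(ds[[m]]$values)
    rel <- norm(xc - A %*% S, "F") / norm(xc, "F")
    expect_lt(rel, 0.15)
  }
})

test_that("with no coupling the constraint stays silent and matches plain infomax", {
  cfg <- small_sim_config(coupled_r = 0, seed = 11L)
  ds <- synthesize_dataset(cfg)
  constrained <- parallel_ica(ds[[1]], ds[[2]], quick_pica_config(seed = 11L))
  plain <- parallel_ica(ds[[1]], ds[[2]], quick_pica_config(seed = 11L, lambda = 0))
  expect_equal(nrow(constrained$constrained_pairs), 0L)
  expect_identical(constrained$modalities[[1]]$W, plain$modalities[[1]]$W)
  expect_identical(constrained$modalities[[2]]$sources, plain$modalities[[2]]$sources)
})

test_that("coupled loadings are recovered at the true pair", {
  cfg <- small_sim_config(seed = 12L, coupled_r = 0.6)
  ds <- synthesize_dataset(cfg)
  fit <- parallel_ica(ds[[1]], ds[[2]], quick_pica_config(seed = 12L))
  best <- which(abs(fit$crossmodal_r) == max(abs(fit$crossmodal_r)), arr.ind = TRUE)
  expect_gte(max(abs(fit$crossmodal_r)), 0.5)
  # map the best estimated pair back to truth components
  m1 <- match_components(fit, ds$truth$sources[[1]], 1)
  m2 <- match_components(fit, ds$truth$sources[[2]], 2)
  expect_equal(m1$permutation[best[1, 1]], cfg$coupled_pair[1])
  expect_equal(m2$permutation[best[1, 2]], cfg$coupled_pair[2])
})

test_that("mismatched subject panels are rejected", {
  cfg <- small_sim_config(seed = 13L)
  ds <- synthesize_dataset(cfg)
  expect_error(
    parallel_ica(ds[[1]]$values[1:10, ], ds[[2]]$values[1:12, ],
                 quick_pica_config()),
    class = "picafuse_domain_error"
  )
})

test_that("identical seeds give identical fits", {
  cfg <- small_sim_config(seed = 14L)
  ds <- synthesize_dataset(cfg)
  f1 <- parallel_ica(ds[[1]], ds[[2]], quick_pica_config(seed = 3L))
  f2 <- parallel_ica(ds[[1]], ds[[2]], quick_pica_config(seed = 3L))
  expect_identical(f1$modalities[[1]]$sources, f2$modalities[[1]]$sources)
  expect_identical(f1$crossmodal_r, f2$crossmodal_r)
})

test_that("tidy/glance/autoplot expose the fit summaries", {
  cfg <- small_sim_config(seed = 15L)
  ds <- synthesize_dataset(cfg)
  fit <- parallel_ica(ds[[1]], ds[[2]], quick_pica_config(seed = 15L))
  pairs <- tidy(fit)
  expect_equal(nrow(pairs), 16L)
  expect_true(all(abs(pairs$r) <= 1))
  comp <- tidy(fit, "components")
  expect_equal(nrow(comp), 8L)
  g <- glance(fit)
  expect_true(g$converged)
  expect_s3_class(autoplot(fit), "ggplot")
})
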