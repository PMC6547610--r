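#' Z-score a spatial source map
#'
#' Standardises a component map over its in-mask voxels (sample SD), the
#' usual preparation before thresholding a map at |z| > 2.5 for display and
#' peak reporting.
#'
#' @param source_row Numeric vector, one value per in-mask voxel.
#' @return Numeric vector with mean 0 and sample SD 1.
#' @export
zscore_map <- function(source_row) {
  if (length(source_row) < 2L) {
    stopf("z-scoring needs at least 2 voxels.", class = "picafuse_domain_error")
  }
  s <- sd(source_row)
  if (!is.finite(s) || s == 0) {
    stopf("zero variance map cannot be z-scored.", class = "picafuse_domain_error")
  }
  (source_row - mean(source_row)) / s
}

#' Threshold a z-map
#'
#' Strict threshold: a voxel survives iff `|z| > cutoff`.
#'
#' @param zmap Numeric vector or array of z values.
#' @param cutoff Positive threshold (default 2.5).
#' @return List: `mask` (logical, same shape as `zmap`) and `n_voxels`.
#' @export
threshold_map <- function(zmap, cutoff = 2.5) {
  check_positive_scalar(cutoff, "cutoff")
  mask <- abs(zmap) > cutoff
  list(mask = mask, n_voxels = sum(mask))
}

#' Group tests on component loadings
#'
#' Welch two-sample t-test of each component's loading column between the two
#' groups — the component-level significance criterion that decides which
#' components contribute ROI features downstream.
#'
#' @param A Subjects x components loading matrix.
#' @param labels Two-level factor/character vector of group labels, aligned
#'   with the rows of `A`.
#' @param alpha Significance level for the `significant` flag.
#' @param modality Optional modality tag copied into the output.
#' @return Tibble: `modality`, `component`, `t`, `df`, `p`, `significant`.
#' @export
loading_group_test <- function(A, labels, alpha = 0.05, modality = NA_character_) {
  A <- as.matrix(A)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) {
    stopf("`labels` must have exactly 2 levels.", class = "picafuse_domain_error")
  }
  if (min(table(labels)) < 2L) {
    stopf("each group needs at least 2 subjects.", class = "picafuse_domain_error")
  }
  res <- map(seq_len(ncol(A)), function(comp) {
    x <- A[labels == levels(labels)[1], comp]
    y <- A[labels == levels(labels)[2], comp]
    if (var(x) == 0 && var(y) == 0) {
      stopf("component %d has zero loading variance in both groups.", comp,
            class = "picafuse_degenerate_error")
    }
    ht <- t.test(x, y)
    tibble(component = comp, t = unname(ht$statistic),
           df = unname(ht$parameter), p = ht$p.value)
  })
  bind_rows(res) |>
    mutate(modality = modality, significant = .data$p < alpha, .before = 1L) |>
    select("modality", "component", "t", "df", "p", "significant")
}

#' Voxel-wise two-sample group test
#'
#' Welch t-test at every in-mask voxel (vectorised). Voxels with zero
#' variance in both groups get `NA` statistics and are counted in a message.
#'
#' @param x A [voxel_matrix()] or subjects x voxels matrix.
#' @param labels Two-level group labels aligned with rows.
#' @return Tibble: `voxel` (column index), `t`, `df`, `p`.
#' @export
voxelwise_group_test <- function(x, labels) {
  values <- if (inherits(x, "voxel_matrix")) x$values else as.matrix(x)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) {
    stopf("`labels` must have exactly 2 levels.", class = "picafuse_domain_error")
  }
  g1 <- values[labels == levels(labels)[1], , drop = FALSE]
  g2 <- values[labels == levels(labels)[2], , drop = FALSE]
  n1 <- nrow(g1); n2 <- nrow(g2)
  if (n1 < 2L || n2 < 2L) {
    stopf("each group needs at least 2 subjects.", class = "picafuse_domain_error")
  }
  v1 <- col_sds(g1)^2 / n1
  v2 <- col_sds(g2)^2 / n2
  se2 <- v1 + v2
  t_stat <- (colMeans(g1) - colMeans(g2)) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  degenerate <- se2 == 0
  t_stat[degenerate] <- NA_real_
  df[degenerate] <- NA_real_
  if (any(degenerate)) {
    message(sprintf("%d zero-variance voxel(s) flagged NA in the voxel-wise test.",
                    sum(degenerate)))
  }
  tibble(voxel = seq_along(t_stat), t = t_stat, df = df,
         p = 2 * pt(-abs(t_stat), df))
}

#' All-pairs cross-modal loading correlations with FDR
#'
#' Pearson correlation of every modality-1 loading column with every
#' modality-2 loading column, two-sided p via the t transform
#' (`t = r sqrt((n-2)/(1-r^2))`, df = n - 2), and Benjamini-Hochberg
#' adjustment across all pairs.
#'
#' @param A1,A2 Loading matrices with identical subject rows.
#' @param alpha FDR level for the `pass` flag.
#' @return Tibble: `i`, `j`, `r`, `p`, `q`, `pass`, one row per pair.
#' @export
crossmodal_correlations <- function(A1, A2, alpha = 0.05) {
  A1 <- as.matrix(A1); A2 <- as.matrix(A2)
  if (nrow(A1) != nrow(A2)) {
    stopf("loading matrices have different subject counts (%d vs %d).",
          nrow(A1), nrow(A2), class = "picafuse_domain_error")
  }
  n <- nrow(A1)
  rmat <- cor(A1, A2)
  grid <- tidyr::expand_grid(i = seq_len(ncol(A1)), j = seq_len(ncol(A2)))
  r <- rmat[cbind(grid$i, grid$j)]
  t_stat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(t_stat), n - 2)
  fdr <- bh_fdr(p, alpha = alpha)
  grid |>
    mutate(r = r, p = p, q = fdr$q, pass = fdr$reject)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up adjustment of a p-value vector; rejection at `q < alpha`.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @param alpha FDR level.
#' @return Tibble: `p`, `q`, `reject`.
#' @export
bh_fdr <- function(pvalues, alpha = 0.05) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stopf("p-values must lie in [0, 1].", class = "picafuse_domain_error")
  }
  q <- p.adjust(pvalues, method = "BH")
  tibble(p = pvalues, q = q, reject = q < alpha)
}

#' Covariate associations of component loadings
#'
#' Screens each component's loadings for association with age (Pearson
#' correlation) and sex (Welch t), and can return loadings residualised on
#' both covariates for sensitivity analyses.
#'
#' @param A Subjects x components loading matrix.
#' @param age Numeric vector.
#' @param sex Two-level factor/character vector.
#' @param residualize If `TRUE`, attach the residualised loading matrix as
#'   attribute `"residualized"`.
#' @return Tibble: `component`, `age_r`, `age_p`, `sex_t`, `sex_p`.
#' @export
covariate_check <- function(A, age, sex, residualize = FALSE) {
  A <- as.matrix(A)
  sex <- as.factor(sex)
  if (length(unique(age)) < 2L || nlevels(sex) < 2L) {
    stopf("constant covariate supplied.", class = "picafuse_domain_error")
  }
  out <- map(seq_len(ncol(A)), function(comp) {
    ct <- cor.test(A[, comp], age)
    tt <- t.test(A[sex == levels(sex)[1], comp], A[sex == levels(sex)[2], comp])
    tibble(component = comp,
           age_r = unname(ct$estimate), age_p = ct$p.value,
           sex_t = unname(tt$statistic), sex_p = tt$p.value)
  }) |> bind_rows()
  if (residualize) {
    resid_mat <- apply(A, 2L, function(col) residuals(lm(col ~ age + sex)))
    attr(out, "residualized") <- resid_mat
  }
  out
}

#' Welch two-sample t-test from summary statistics
#'
#' The same test as `t.test(x, y)` but computed from group means, SDs and
#' sizes — the form needed to check a published demographics table.
#'
#' @param mean1,sd1,n1 Group 1 summary.
#' @param mean2,sd2,n2 Group 2 summary.
#' @return Tibble: `t`, `df` (Welch-Satterthwaite), `p` (two-sided).
#' @export
welch_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  t_stat <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  tibble(t = t_stat, df = df, p = 2 * pt(-abs(t_stat), df))
}

#' Demographic comparison table
#'
#' Compares the two groups of a subject table the way cohort tables are
#' reported: Welch t for continuous measures (age, MMSE, and any CSF
#' columns present), chi-square without continuity correction for sex and
#' APOE4 carriage, and a Mann-Whitney test (normal approximation with tie
#' correction) for CDR.
#'
#' @param subject_table Data frame with columns `group` plus any of `age`,
#'   `mmse`, `sex`, `apoe4`, `cdr`, `csf_tau`, `csf_abeta`.
#' @return Tibble: `variable`, `group1`, `group2` (formatted summaries),
#'   `statistic`, `p`, `test`.
#' @export
cohort_table <- function(subject_table) {
  if (!"group" %in% names(subject_table)) {
    stopf("subject table lacks a `group` column.", class = "picafuse_domain_error")
  }
  g <- as.factor(subject_table$group)
  lv <- levels(g)
  fmt_ms <- function(x) sprintf("%.1f ± %.1f", mean(x), sd(x))
  rows <- list()
  add <- function(row) rows[[length(rows) + 1L]] <<- row

  for (v in intersect(c("age", "mmse", "csf_tau", "csf_abeta"), names(subject_table))) {
    x <- subject_table[[v]][g == lv[1]]
    y <- subject_table[[v]][g == lv[2]]
    ht <- t.test(x, y)
    add(tibble(variable = v, group1 = fmt_ms(x), group2 = fmt_ms(y),
               statistic = unname(ht$statistic), p = ht$p.value,
               test = "two-sample t"))
  }
  for (v in intersect(c("sex", "apoe4"), names(subject_table))) {
    tab <- table(g, subject_table[[v]])
    ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
    counts <- apply(tab, 1L, paste, collapse = ":")
    add(tibble(variable = v, group1 = counts[lv[1]], group2 = counts[lv[2]],
               statistic = unname(ht$statistic), p = ht$p.value,
               test = "chi-square"))
  }
  if ("cdr" %in% names(subject_table)) {
    x <- subject_table$cdr[g == lv[1]]
    y <- subject_table$cdr[g == lv[2]]
    ht <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
    add(tibble(variable = "cdr",
               group1 = sprintf("%.2f", stats::median(x)),
               group2 = sprintf("%.2f", stats::median(y)),
               statistic = unname(ht$statistic), p = ht$p.value,
               test = "Mann-Whitney"))
  }
  bind_rows(rows)
}
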