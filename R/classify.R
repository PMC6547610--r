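#' ROI features from component masks
#'
#' One feature per component mask: the subject's mean intensity over the
#' mask's voxels — the ROI summary carried forward from each significantly
#' group-different component.
#'
#' @param vm A [voxel_matrix()].
#' @param component_masks Named list of logical vectors (one entry per
#'   in-mask voxel) or logical 3-D arrays on the analysis grid.
#' @param condition Condition tag stored on the result (`"Non"`, `"Tau"`,
#'   `"Abeta"`, `"All"` in the standard experiment).
#' @return A `feature_table`: tibble with `subject_id` plus one numeric
#'   column per mask, with attribute `condition`.
#' @export
extract_roi_features <- function(vm, component_masks, condition = NA_character_) {
  stopifnot(inherits(vm, "voxel_matrix"))
  if (is.null(names(component_masks))) {
    names(component_masks) <- sprintf("%s_IC%d", vm$modality,
                                      seq_along(component_masks))
  }
  cols <- imap(component_masks, function(mask, nm) {
    if (is.array(mask)) mask <- mask[vm$mask]
    if (length(mask) != ncol(vm$values)) {
      stopf("mask '%s' does not match the voxel columns.", nm,
            class = "picafuse_domain_error")
    }
    if (!any(mask)) {
      stopf("component mask '%s' is empty.", nm, class = "picafuse_domain_error")
    }
    unname(rowMeans(vm$values[, mask, drop = FALSE]))
  })
  out <- as_tibble(c(list(subject_id = vm$subject_ids), cols))
  attr(out, "condition") <- condition
  class(out) <- c("feature_table", class(out))
  out
}

#' Assemble the four feature conditions
#'
#' Builds the Non / Tau / Abeta / All feature tables from a fitted
#' decomposition: per modality, one mean-intensity feature per significant
#' component (its thresholded |z| mask); `All` concatenates both modalities;
#' `Non` is the raw-data baseline — each modality's whole-mask mean plus the
#' top-5 principal-component scores of the column-concatenated raw data,
#' a deliberately weak comparison condition.
#'
#' @param fit A `pica_fit` fitted on [voxel_matrix()] inputs.
#' @param vm1,vm2 The voxel matrices the fit used.
#' @param tests1,tests2 [loading_group_test()] tibbles per modality.
#' @param z_cutoff Threshold for the component masks.
#' @return Named list of four `feature_table`s.
#' @export
build_feature_tables <- function(fit, vm1, vm2, tests1, tests2, z_cutoff = 2.5) {
  masks_of <- function(modality, tests) {
    sig <- tests$component[tests$significant]
    masks <- map(sig, function(comp) {
      threshold_map(zscore_map(fit$modalities[[modality]]$sources[comp, ]),
                    cutoff = z_cutoff)$mask
    })
    names(masks) <- sprintf("%s_IC%d",
                            fit$modalities[[modality]]$modality, sig)
    masks
  }
  m1 <- masks_of(1L, tests1)
  m2 <- masks_of(2L, tests2)
  if (!length(m1) || !length(m2)) {
    stopf("no significant components in at least one modality; cannot build ROI features.",
          class = "picafuse_degenerate_error")
  }
  tau_ft <- extract_roi_features(vm1, m1, condition = "Tau")
  ab_ft <- extract_roi_features(vm2, m2, condition = "Abeta")
  all_ft <- left_join(tau_ft, ab_ft, by = "subject_id")
  attr(all_ft, "condition") <- "All"
  class(all_ft) <- class(tau_ft)

  raw <- cbind(vm1$values, vm2$values)
  pcs <- stats::prcomp(raw, rank. = 5L, center = TRUE, scale. = FALSE)$x
  non_ft <- tibble(subject_id = vm1$subject_ids,
                   mean_m1 = rowMeans(vm1$values),
                   mean_m2 = rowMeans(vm2$values))
  non_ft <- as_tibble(cbind(non_ft, as_tibble(pcs)))
  attr(non_ft, "condition") <- "Non"
  class(non_ft) <- class(tau_ft)
  list(Non = non_ft, Tau = tau_ft, Abeta = ab_ft, All = all_ft)
}

#' Stratified k-fold assignment
#'
#' Partitions subjects into `k` folds so that fold sizes differ by at most
#' one and each fold's class counts differ from exact proportionality by at
#' most one subject. Deterministic given the seed.
#'
#' @param labels Class labels.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..k`, aligned with `labels`.
#' @export
stratified_kfold <- function(labels, k = 5L, seed = 1L) {
  labels <- as.factor(labels)
  counts <- table(labels)
  if (any(counts < k)) {
    stopf("class '%s' has fewer than k = %d members.",
          names(counts)[which.min(counts)], k, class = "picafuse_domain_error")
  }
  folds <- integer(length(labels))
  totals <- integer(k)
  with_seed(seed, {
    for (cl_i in seq_along(levels(labels))) {
      idx <- sample(which(labels == levels(labels)[cl_i]))
      n_c <- length(idx)
      base <- n_c %/% k
      r <- n_c %% k
      per_fold <- rep(base, k)
      if (r > 0L) {
        # spill the remainder into the currently smallest folds, so overall
        # fold sizes never drift apart by more than one subject
        spill <- order(totals, seq_len(k))[seq_len(r)]
        per_fold[spill] <- per_fold[spill] + 1L
      }
      folds[idx] <- rep(seq_len(k), per_fold)
      totals <- totals + per_fold
    }
  })
  folds
}

#' Rank-based ROC AUC
#'
#' Area under the ROC curve via the rank (Mann-Whitney) formulation with
#' half credit for tied scores.
#'
#' @param scores Numeric classifier scores, higher = more positive-like.
#' @param labels Class labels.
#' @param positive Which level counts as positive (default: first factor
#'   level).
#' @return Scalar AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  labels <- as.factor(labels)
  if (is.null(positive)) positive <- levels(labels)[1]
  pos <- labels == positive
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    stopf("both classes must be present to compute an AUC.",
          class = "picafuse_domain_error")
  }
  r <- rank(scores)  # midranks: ties get half credit
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Fit the default classifier (L2-penalised logistic regression) on
# standardised training features; returns a scoring closure.
fit_linear_classifier <- function(x_train, y_train, positive) {
  mu <- colMeans(x_train)
  sigma <- col_sds(x_train)
  sigma[sigma == 0] <- 1
  xs <- sweep(sweep(x_train, 2L, mu), 2L, sigma, "/")
  y <- as.integer(y_train == positive)
  if (length(unique(y)) < 2L) {
    stopf("training fold contains a single class.",
          class = "picafuse_degenerate_error")
  }
  if (ncol(xs) >= 2L) {
    model <- glmnet::glmnet(xs, y, family = "binomial", alpha = 0,
                            lambda = 1 / length(y), standardize = FALSE)
    score_fun <- function(x_new) {
      xn <- sweep(sweep(x_new, 2L, mu), 2L, sigma, "/")
      as.numeric(predict(model, xn, type = "link"))
    }
  } else {
    df <- data.frame(y = y, x = xs[, 1])
    model <- suppressWarnings(stats::glm(y ~ x, df, family = stats::binomial()))
    score_fun <- function(x_new) {
      xn <- sweep(sweep(x_new, 2L, mu), 2L, sigma, "/")
      as.numeric(predict(model, data.frame(x = xn[, 1]), type = "link"))
    }
  }
  score_fun
}

#' Stratified k-fold cross-validated classification
#'
#' For each fold: standardisation and the classifier (ridge-penalised
#' logistic regression; decision values as scores) are fitted on the
#' training folds only, then the held-out fold is scored. Reports per-fold
#' and mean accuracy, AUC, sensitivity (true-positive rate on the positive
#' class) and specificity, all on the percent scale, the mean being the
#' arithmetic mean of the k fold values.
#'
#' @param features A `feature_table` (or data frame with `subject_id`).
#' @param labels Two-class labels aligned with the feature rows.
#' @param k Number of folds.
#' @param seed Fold seed.
#' @param positive Positive class (default `"MCI"` if present, else the
#'   first level).
#' @return Object of class `classification_report`: `folds` (per-fold
#'   tibble), `mean` (1-row tibble), `condition`, `fold_assignment`,
#'   `scores` (pooled out-of-fold scores), `classifier`, `seed`.
#' @export
cross_validate <- function(features, labels, k = 5L, seed = 1L, positive = NULL) {
  x <- as.matrix(features[setdiff(names(features), "subject_id")])
  storage.mode(x) <- "double"
  labels <- as.factor(labels)
  if (is.null(positive)) {
    positive <- if ("MCI" %in% levels(labels)) "MCI" else levels(labels)[1]
  }
  folds <- stratified_kfold(labels, k = k, seed = seed)
  oof_scores <- numeric(length(labels))
  fold_rows <- map(seq_len(k), function(f) {
    tr <- folds != f
    scorer <- fit_linear_classifier(x[tr, , drop = FALSE], labels[tr], positive)
    sc <- scorer(x[!tr, , drop = FALSE])
    oof_scores[!tr] <<- sc
    truth <- labels[!tr] == positive
    pred <- sc > 0
    tibble(fold = f,
           acc = 100 * mean(pred == truth),
           auc = 100 * roc_auc(sc, labels[!tr], positive = positive),
           sen = 100 * mean(pred[truth]),
           spe = 100 * mean(!pred[!truth]))
  })
  folds_tbl <- bind_rows(fold_rows)
  structure(
    list(folds = folds_tbl,
         mean = summarise(folds_tbl, across(c("acc", "auc", "sen", "spe"), mean)),
         condition = attr(features, "condition") %||% NA_character_,
         fold_assignment = folds,
         scores = oof_scores,
         labels = labels,
         positive = positive,
         classifier = "L2-penalised logistic regression (glmnet, alpha = 0, lambda = 1/n)",
         seed = seed),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  m <- x$mean
  cat(sprintf("<classification_report> %s: ACC %.2f | AUC %.2f | SEN %.2f | SPE %.2f (mean of %d folds)\n",
              x$condition, m$acc, m$auc, m$sen, m$spe, nrow(x$folds)))
  invisible(x)
}

#' @rdname cross_validate
#' @param x A `classification_report`.
#' @param ... Unused.
#' @method tidy classification_report
#' @export
tidy.classification_report <- function(x, ...) {
  x$folds |> mutate(condition = x$condition, .before = 1L)
}

#' @rdname cross_validate
#' @method glance classification_report
#' @export
glance.classification_report <- function(x, ...) {
  x$mean |> mutate(condition = x$condition, seed = x$seed, .before = 1L)
}
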