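#' Tidy a parallel-ICA fit
#'
#' `tidy()` returns one row per cross-modal loading pair (`i`, `j`, `r`,
#' whether the pair was under the constraint); with `what = "components"` it
#' returns one row per component with loading-scale summaries.
#'
#' @param x A `pica_fit`.
#' @param what `"pairs"` (default) or `"components"`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy pica_fit
#' @export
tidy.pica_fit <- function(x, what = c("pairs", "components"), ...) {
  what <- match.arg(what)
  if (what == "pairs") {
    rmat <- x$crossmodal_r
    out <- tidyr::expand_grid(i = seq_len(nrow(rmat)), j = seq_len(ncol(rmat))) |>
      mutate(r = rmat[cbind(.data$i, .data$j)])
    out |>
      left_join(x$constrained_pairs |> mutate(constrained = TRUE) |> select(-"r"),
                by = c("i", "j")) |>
      mutate(constrained = !is.na(.data$constrained))
  } else {
    bind_rows(map(x$modalities, function(m) {
      tibble(modality = m$modality,
             component = seq_len(ncol(m$loadings)),
             loading_sd = col_sds(m$loadings),
             source_skewness = row_skewness(m$sources))
    }))
  }
}

#' Glance at a parallel-ICA fit
#'
#' @param x A `pica_fit`.
#' @param ... Unused.
#' @return One-row tibble: component counts, epochs, convergence, the
#'   strongest cross-modal loading correlation and the constrained-pair
#'   count.
#' @method glance pica_fit
#' @export
glance.pica_fit <- function(x, ...) {
  best <- which(abs(x$crossmodal_r) == max(abs(x$crossmodal_r)), arr.ind = TRUE)[1, ]
  tibble(
    n_components_1 = ncol(x$modalities[[1]]$loadings),
    n_components_2 = ncol(x$modalities[[2]]$loadings),
    epochs = nrow(x$log),
    converged = x$converged,
    max_crossmodal_r = x$crossmodal_r[best[1], best[2]],
    best_pair_i = unname(best[1]),
    best_pair_j = unname(best[2]),
    n_constrained = nrow(x$constrained_pairs)
  )
}

#' Heatmap of cross-modal loading correlations
#'
#' @param object A `pica_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pica_fit
#' @export
autoplot.pica_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$j), y = factor(.data$i),
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = df[df$constrained, ], shape = 8) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = sprintf("%s component", names(object$modalities)[2]),
                  y = sprintf("%s component", names(object$modalities)[1]),
                  fill = "loading r",
                  title = "Cross-modal loading correlations",
                  subtitle = "* = constrained pair") +
    ggplot2::theme_minimal()
}

#' Criterion curves of a model-order estimate
#'
#' @param object An `order_estimate`.
#' @param ... Unused.
#' @return A ggplot of the AIC and MDL curves with the chosen order marked.
#' @method autoplot order_estimate
#' @export
autoplot.order_estimate <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("aic", "mdl"), names_to = "criterion",
                        values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$order, y = .data$value,
                                   colour = .data$criterion)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$chosen_order, linetype = 2) +
    ggplot2::labs(x = "candidate order", y = "criterion value",
                  title = sprintf("Model-order selection (AIC minimum at %d)",
                                  object$chosen_order)) +
    ggplot2::theme_minimal()
}

# Empirical ROC coordinates from pooled out-of-fold scores.
roc_coordinates <- function(scores, labels, positive) {
  ord <- order(scores, decreasing = TRUE)
  pos <- labels[ord] == positive
  tibble(fpr = c(0, cumsum(!pos) / sum(!pos)),
         tpr = c(0, cumsum(pos) / sum(pos)))
}

#' ROC curve of a cross-validated classifier
#'
#' Drawn from the pooled out-of-fold scores (only available for the
#' fixed-components protocol, which retains them).
#'
#' @param object A `classification_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot classification_report
#' @export
autoplot.classification_report <- function(object, ...) {
  if (is.null(object$scores)) {
    stopf("no pooled scores stored on this report; ROC display needs the fixed-components protocol.",
          class = "picafuse_domain_error")
  }
  df <- roc_coordinates(object$scores, object$labels, object$positive)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("ROC — %s (mean fold AUC %.1f%%)",
                                  object$condition, object$mean$auc)) +
    ggplot2::theme_minimal()
}

#' Compare mean metrics across feature conditions
#'
#' @param reports Named list of `classification_report`s (e.g. the
#'   `reports` element of a pipeline's classification stage).
#' @return A ggplot bar chart of mean ACC/AUC/SEN/SPE per condition.
#' @export
plot_condition_metrics <- function(reports) {
  df <- bind_rows(map(reports, glance)) |>
    tidyr::pivot_longer(c("acc", "auc", "sen", "spe"),
                        names_to = "metric", values_to = "value") |>
    mutate(metric = toupper(.data$metric))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "feature condition", y = "mean over folds (%)",
                  title = "Cross-validated classification by feature condition") +
    ggplot2::theme_minimal()
}
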