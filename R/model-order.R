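#' Information-theoretic model-order selection
#'
#' Estimates the number of latent components of a subjects x voxels matrix
#' from the eigenvalues of its between-subject covariance, using the
#' Wax-Kailath formulation of AIC and MDL. For each candidate order `k` the
#' log-likelihood term is `N (p - k) log(a_k / g_k)`, where `g_k` and `a_k`
#' are the geometric and arithmetic means of the trailing `p - k` sample
#' eigenvalues, `p` is the observed dimension (subjects) and `N` the number
#' of samples (in-mask voxels). The criteria are
#' `AIC(k) = 2 N (p - k) log(a_k/g_k) + 2 k (2p - k)` and
#' `MDL(k) = N (p - k) log(a_k/g_k) + 0.5 k (2p - k) log N`;
#' the chosen order is the AIC minimiser (MDL's curve is reported alongside,
#' as the more conservative criterion, but is not used for selection).
#'
#' Eigenvalues are floored at `1e-12` times the largest before the log so
#' that exactly low-rank (noise-free) input yields finite curves. In the
#' spatial-decomposition orientation voxels are not independent samples
#' (spatial smoothness inflates `N`); no correction is applied and the
#' returned object carries that caveat.
#'
#' @param x A [voxel_matrix()] or a numeric matrix (subjects x voxels).
#' @param max_order Largest candidate order; defaults to `p - 1`.
#' @return An object of class `order_estimate` with fields `chosen_order`,
#'   `aic_curve`, `mdl_curve` (named by candidate order `0..max_order`),
#'   `eigenvalues`, and `caveat`.
#' @export
estimate_order <- function(x, max_order = NULL) {
  values <- if (inherits(x, "voxel_matrix")) x$values else as.matrix(x)
  p <- nrow(values)
  n_samp <- ncol(values)
  if (p < 3L) {
    stopf("order estimation needs at least 3 observations, got %d.", p,
          class = "picafuse_domain_error")
  }
  if (is.null(max_order)) max_order <- p - 1L
  if (max_order >= min(p, n_samp)) {
    stopf("`max_order` (%d) must be below min(subjects, voxels) = %d.",
          max_order, min(p, n_samp), class = "picafuse_domain_error")
  }
  xc <- values - rowMeans(values)
  ev <- eigen(tcrossprod(xc) / n_samp, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8 * max(ev))) {
    stopf("negative covariance eigenvalue beyond numerical tolerance.",
          class = "picafuse_numerical_error")
  }
  ev <- sort(pmax(ev, 1e-12 * max(ev)), decreasing = TRUE)

  ks <- 0:max_order
  loglik_term <- vapply(ks, function(k) {
    tail_ev <- ev[(k + 1):p]
    # log(arithmetic/geometric mean) of trailing eigenvalues, >= 0
    (p - k) * (log(mean(tail_ev)) - mean(log(tail_ev)))
  }, numeric(1))
  aic <- 2 * n_samp * loglik_term + 2 * ks * (2 * p - ks)
  mdl <- n_samp * loglik_term + 0.5 * ks * (2 * p - ks) * log(n_samp)
  names(aic) <- names(mdl) <- ks

  structure(
    list(chosen_order = ks[which.min(aic)],
         aic_curve = aic, mdl_curve = mdl,
         mdl_order = ks[which.min(mdl)],
         eigenvalues = ev, n_samples = n_samp, n_observed = p,
         caveat = paste("effective sample size taken as the voxel count;",
                        "spatial smoothness violates the i.i.d. sample",
                        "assumption and no subsampling correction is applied")),
    class = "order_estimate"
  )
}

#' @export
print.order_estimate <- function(x, ...) {
  cat(sprintf("<order_estimate> AIC order %d (MDL order %d), p = %d, N = %d\n",
              x$chosen_order, x$mdl_order, x$n_observed, x$n_samples))
  invisible(x)
}

#' @rdname estimate_order
#' @param x An `order_estimate`.
#' @param ... Unused.
#' @method tidy order_estimate
#' @export
tidy.order_estimate <- function(x, ...) {
  tibble(order = as.integer(names(x$aic_curve)),
         aic = unname(x$aic_curve),
         mdl = unname(x$mdl_curve))
}

#' @rdname estimate_order
#' @method glance order_estimate
#' @export
glance.order_estimate <- function(x, ...) {
  tibble(chosen_order = x$chosen_order,
         mdl_order = x$mdl_order,
         n_observed = x$n_observed,
         n_samples = x$n_samples)
}
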