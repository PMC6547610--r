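#' Configuration for the parallel-ICA engine
#'
#' Hyperparameters of the constrained infomax decomposition. None of these
#' are dictated by the decomposition model itself; they control the
#' optimiser and the cross-modal constraint and are all surfaced here with
#' logged defaults.
#'
#' @param n_components Components per modality (single value or length-2).
#'   The pipeline default is 8.
#' @param learning_rate Initial natural-gradient step size.
#' @param anneal_factor Multiplier applied to the learning rate after a
#'   divergence-triggered restart.
#' @param max_iterations Epoch cap for the alternating optimisation.
#' @param tolerance Convergence threshold on the maximum absolute
#'   unmixing-weight change per epoch.
#' @param constraint_threshold Cross-modal loading |correlation| at which a
#'   pair becomes eligible for the enhancing constraint.
#' @param lambda Initial constraint strength; halved whenever a constrained
#'   pair's |r| jumps by more than 0.05 within one epoch (anti-overshoot).
#'   `lambda = 0` disables the constraint, giving plain per-modality infomax.
#' @param max_constrained_pairs Maximum number of simultaneously constrained
#'   pairs (default 1: the method targets a single strongly coupled pair).
#' @param burn_in Epochs of unconstrained infomax before the constraint
#'   becomes eligible.
#' @param seed Seed for the unmixing-weight initialisation.
#' @return A list of class `pica_config`.
#' @export
pica_config <- function(n_components = 8L,
                        learning_rate = 0.02,
                        anneal_factor = 0.9,
                        max_iterations = 2000L,
                        tolerance = 1e-6,
                        constraint_threshold = 0.3,
                        lambda = 0.05,
                        max_constrained_pairs = 1L,
                        burn_in = 20L,
                        seed = 1L) {
  if (length(n_components) == 1L) n_components <- rep(n_components, 2L)
  if (constraint_threshold <= 0 || constraint_threshold >= 1) {
    stopf("`constraint_threshold` must lie strictly inside (0, 1).",
          class = "picafuse_domain_error")
  }
  if (lambda < 0) {
    stopf("`lambda` must be nonnegative.", class = "picafuse_domain_error")
  }
  check_positive_scalar(learning_rate, "learning_rate")
  structure(
    list(n_components = as.integer(n_components),
         learning_rate = learning_rate,
         anneal_factor = anneal_factor,
         max_iterations = as.integer(max_iterations),
         tolerance = tolerance,
         constraint_threshold = constraint_threshold,
         lambda = lambda,
         max_constrained_pairs = as.integer(max_constrained_pairs),
         burn_in = as.integer(burn_in),
         seed = as.integer(seed)),
    class = "pica_config"
  )
}

#' PCA whitening of a subjects x voxels matrix
#'
#' Rows are centred (each subject's mean over in-mask voxels removed), the
#' between-subject covariance is eigendecomposed, and the top `k` principal
#' axes are retained. The whitened data `K %*% xc` has identity row
#' covariance; the dewhitening map inverts the whitening on the retained
#' subspace.
#'
#' @param x A [voxel_matrix()] or numeric matrix (subjects x voxels).
#' @param k Number of principal axes to retain; must not exceed the rank of
#'   the centred data.
#' @return List: `xw` (k x voxels whitened data), `whitener` (k x subjects),
#'   `dewhitener` (subjects x k), `row_means`, `eigenvalues`,
#'   `var_retained` (fraction of total variance in the top k axes).
#' @export
whiten <- function(x, k) {
  values <- if (inherits(x, "voxel_matrix")) x$values else as.matrix(x)
  n <- nrow(values)
  v <- ncol(values)
  row_means <- rowMeans(values)
  xc <- values - row_means
  cmat <- tcrossprod(xc) / (v - 1)
  eig <- eigen(cmat, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  rank <- sum(ev > 1e-10 * max(ev))
  if (k > rank) {
    stopf("requested k = %d exceeds the measured rank %d of the centred data.",
          k, rank, class = "picafuse_rank_error")
  }
  top <- seq_len(k)
  whitener <- diag(1 / sqrt(ev[top]), k) %*% t(eig$vectors[, top, drop = FALSE])
  dewhitener <- eig$vectors[, top, drop = FALSE] %*% diag(sqrt(ev[top]), k)
  list(xw = whitener %*% xc,
       whitener = whitener,
       dewhitener = dewhitener,
       row_means = row_means,
       eigenvalues = ev,
       var_retained = sum(ev[top]) / sum(ev))
}

#' One natural-gradient infomax update
#'
#' The maximum-entropy update with a logistic nonlinearity:
#' `W <- W + eta * (I + (1 - 2 g(U)) U' / N) W` with `U = W X` and
#' `g` the logistic function, i.e. the natural gradient of the infomax
#' log-likelihood (see [infomax_objective()]). Signals divergence (condition
#' class `picafuse_divergence`) when any weight magnitude exceeds `1e9`; the
#' engine responds by annealing the learning rate and restarting the epoch.
#'
#' @param W Square unmixing matrix (components x components).
#' @param batch Whitened data block (components x samples).
#' @param learning_rate Step size `eta`.
#' @return Updated `W`.
#' @export
infomax_step <- function(W, batch, learning_rate) {
  if (!all(is.finite(W))) {
    stopf("`W` contains non-finite entries.", class = "picafuse_numerical_error")
  }
  u <- W %*% batch
  y <- plogis(u)
  k <- nrow(W)
  grad <- diag(k) + (1 - 2 * y) %*% t(u) / ncol(batch)
  w_new <- W + learning_rate * grad %*% W
  if (any(abs(w_new) > 1e9)) {
    abort("infomax update diverged (|W| > 1e9); anneal the learning rate and restart.",
          class = "picafuse_divergence")
  }
  w_new
}

#' Infomax log-likelihood (per-sample mean)
#'
#' `log |det W| + mean over samples of sum_i log g'(u_i)` with logistic `g`.
#' Exposed so the natural-gradient step can be checked against numerical
#' differentiation.
#'
#' @param W Square unmixing matrix.
#' @param batch Whitened data (components x samples).
#' @return Scalar objective value.
#' @export
infomax_objective <- function(W, batch) {
  u <- W %*% batch
  y <- plogis(u)
  det_term <- determinant(W, logarithm = TRUE)
  as.numeric(det_term$modulus) + mean(colSums(log(pmax(y * (1 - y), 1e-300))))
}

# Gradient of r(a, b)^2 with respect to a (b held fixed).
corr_sq_grad <- function(a, b) {
  ac <- a - mean(a)
  bc <- b - mean(b)
  na <- sqrt(sum(ac^2))
  nb <- sqrt(sum(bc^2))
  r <- sum(ac * bc) / (na * nb)
  2 * r * (bc / (na * nb) - r * ac / na^2)
}

# Small random orthogonal perturbation of the identity, seeded.
init_unmixing <- function(k, seed) {
  with_seed(seed, {
    m <- diag(k) + 0.05 * matrix(rnorm(k * k), k, k)
    qr_m <- qr(m)
    q <- qr.Q(qr_m)
    # fix sign so the result is close to +identity
    q %*% diag(sign(diag(qr.R(qr_m))), k)
  })
}

#' Parallel ICA of two paired modalities
#'
#' Decomposes two subjects x voxels matrices that share a subject panel into
#' per-modality independent spatial sources and subject loadings, while
#' adaptively enhancing the correlation between the most strongly coupled
#' cross-modal loading pair. Each modality is whitened to `n_components`
#' principal axes and unmixed by full-batch natural-gradient infomax; after
#' `burn_in` epochs, the cross-modal loading correlations are scanned each
#' epoch and for up to `max_constrained_pairs` pairs whose |r| exceeds
#' `constraint_threshold`, a gradient-ascent step on r^2 (taken with respect
#' to the two loading columns and propagated to the unmixing weights through
#' the dewhitening relation `A = D W^-1`) is applied with strength `lambda`.
#' `lambda` is halved whenever a constrained pair's |r| grows by more than
#' 0.05 in a single epoch, which prevents the constraint from manufacturing
#' correlation that is not in the data. Ties at the activation threshold are
#' broken toward the lexicographically smallest `(i, j)`.
#'
#' On return the scale and sign indeterminacies are fixed: every source row
#' has zero mean and unit variance over the mask with nonnegative skewness,
#' and the loading columns carry the magnitude (the per-subject weight of a
#' component, i.e. its contribution to the between-subject variance).
#'
#' @param data1,data2 [voxel_matrix()] objects (or bare matrices) with the
#'   same subjects in the same order.
#' @param config A [pica_config()].
#' @return An object of class `pica_fit`: per-modality `W`, `sources`,
#'   `loadings`, the whitening metadata, the cross-modal loading-correlation
#'   matrix, the constrained-pair history, a convergence log (tibble), and a
#'   `converged` flag (a warning, not an error, is raised when the epoch cap
#'   is hit first).
#' @export
parallel_ica <- function(data1, data2, config = pica_config()) {
  v1 <- if (inherits(data1, "voxel_matrix")) data1$values else as.matrix(data1)
  v2 <- if (inherits(data2, "voxel_matrix")) data2$values else as.matrix(data2)
  if (nrow(v1) != nrow(v2)) {
    stopf("modalities have different subject counts (%d vs %d).",
          nrow(v1), nrow(v2), class = "picafuse_domain_error")
  }
  ids1 <- rownames(v1)
  ids2 <- rownames(v2)
  if (!is.null(ids1) && !is.null(ids2) && !identical(ids1, ids2)) {
    stopf("subject order differs between modalities.",
          class = "picafuse_domain_error")
  }
  k <- config$n_components

  wh <- list(whiten(v1, k[1]), whiten(v2, k[2]))
  W <- list(init_unmixing(k[1], child_seed(config$seed, 1L)),
            init_unmixing(k[2], child_seed(config$seed, 2L)))

  eta <- rep(config$learning_rate, 2L)
  lambda <- config$lambda
  prev_r <- NA_real_
  active_pairs <- NULL
  log_rows <- vector("list", config$max_iterations)
  converged <- FALSE
  n_restarts <- 0L

  loadings_of <- function(m) wh[[m]]$dewhitener %*% solve(W[[m]])

  for (epoch in seq_len(config$max_iterations)) {
    w_old <- W
    for (m in 1:2) {
      step_ok <- tryCatch({
        W[[m]] <- infomax_step(W[[m]], wh[[m]]$xw, eta[m])
        TRUE
      }, picafuse_divergence = function(e) FALSE)
      if (!step_ok) {
        # blown-up weights cannot be iterated out of: restart this modality
        # from its initial unmixing at an annealed learning rate
        eta[m] <- eta[m] * config$anneal_factor
        n_restarts <- n_restarts + 1L
        W[[m]] <- init_unmixing(k[m], child_seed(config$seed, m))
        if (eta[m] < 1e-8) {
          stopf("learning rate annealed below 1e-8 without a stable step.",
                class = "picafuse_numerical_error")
        }
      }
    }

    constrained_now <- NULL
    if (lambda > 0 && epoch > config$burn_in) {
      A1 <- loadings_of(1L)
      A2 <- loadings_of(2L)
      rmat <- cor(A1, A2)
      eligible <- which(abs(rmat) > config$constraint_threshold, arr.ind = TRUE)
      if (nrow(eligible)) {
        ord <- order(-abs(rmat[eligible]), eligible[, 1], eligible[, 2])
        eligible <- eligible[ord, , drop = FALSE]
        take <- head(seq_len(nrow(eligible)), config$max_constrained_pairs)
        for (t in take) {
          i <- eligible[t, 1]
          j <- eligible[t, 2]
          a <- A1[, i]
          b <- A2[, j]
          # ascend r^2 in loading space; map to mixing columns via A = D M
          m1 <- solve(W[[1]])
          m2 <- solve(W[[2]])
          m1[, i] <- m1[, i] + lambda * crossprod(wh[[1]]$dewhitener, corr_sq_grad(a, b))
          m2[, j] <- m2[, j] + lambda * crossprod(wh[[2]]$dewhitener, corr_sq_grad(b, a))
          # the constraint must not drive the mixing toward singularity
          # (W = M^-1 would explode); skip the step and back off instead
          if (kappa(m1, exact = TRUE) > 1e6 || kappa(m2, exact = TRUE) > 1e6) {
            lambda <- lambda / 2
            next
          }
          W[[1]] <- solve(m1)
          W[[2]] <- solve(m2)
          r_now <- cor(loadings_of(1L)[, i], loadings_of(2L)[, j])
          if (!is.na(prev_r) && abs(r_now) - abs(prev_r) > 0.05) {
            lambda <- lambda / 2
          }
          prev_r <- r_now
          constrained_now <- rbind(constrained_now, c(i, j, r_now))
        }
      }
    }

    dw <- max(max(abs(W[[1]] - w_old[[1]])), max(abs(W[[2]] - w_old[[2]])))
    log_rows[[epoch]] <- tibble(
      iteration = epoch, weight_change = dw, lambda = lambda,
      n_active = if (is.null(constrained_now)) 0L else nrow(constrained_now)
    )
    if (!is.null(constrained_now)) active_pairs <- constrained_now
    if (dw < config$tolerance) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn("parallel ICA reached max_iterations without meeting the weight-change tolerance.")
  }

  fit <- list(modalities = vector("list", 2L), config = config,
              converged = converged, n_restarts = n_restarts,
              log = bind_rows(log_rows))
  for (m in 1:2) {
    S <- W[[m]] %*% wh[[m]]$xw
    A <- wh[[m]]$dewhitener %*% solve(W[[m]])
    # fix scale: unit-variance zero-mean sources, loadings carry magnitude
    s_mean <- rowMeans(S)
    s_sd <- row_sds(S)
    S <- (S - s_mean) / s_sd
    A <- A * rep(s_sd, each = nrow(A))
    # fix sign: nonnegative source skewness
    flip <- ifelse(row_skewness(S) < 0, -1, 1)
    S <- S * flip
    A <- A * rep(flip, each = nrow(A))
    rownames(S) <- colnames(A) <- sprintf("IC%d", seq_len(k[m]))
    if (!is.null(ids1)) rownames(A) <- ids1
    vmod <- if (m == 1L) data1 else data2
    fit$modalities[[m]] <- list(
      W = W[[m]], sources = S, loadings = A,
      whitener = wh[[m]]$whitener, dewhitener = wh[[m]]$dewhitener,
      var_retained = wh[[m]]$var_retained,
      modality = if (inherits(vmod, "voxel_matrix")) vmod$modality else paste0("m", m),
      mask = if (inherits(vmod, "voxel_matrix")) vmod$mask else NULL,
      affine = if (inherits(vmod, "voxel_matrix")) vmod$affine else NULL
    )
  }
  names(fit$modalities) <- vapply(fit$modalities, `[[`, "", "modality")
  fit$crossmodal_r <- cor(fit$modalities[[1]]$loadings, fit$modalities[[2]]$loadings)
  fit$constrained_pairs <- if (is.null(active_pairs)) {
    tibble(i = integer(0), j = integer(0), r = numeric(0))
  } else {
    tibble(i = as.integer(active_pairs[, 1]), j = as.integer(active_pairs[, 2]),
           r = final_pair_r(fit, active_pairs))
  }
  class(fit) <- "pica_fit"
  fit
}

# Final (post sign/scale fixing) correlation for the constrained pairs.
final_pair_r <- function(fit, pairs) {
  vapply(seq_len(nrow(pairs)), function(t) {
    cor(fit$modalities[[1]]$loadings[, pairs[t, 1]],
        fit$modalities[[2]]$loadings[, pairs[t, 2]])
  }, numeric(1))
}

#' @export
print.pica_fit <- function(x, ...) {
  k <- vapply(x$modalities, function(m) ncol(m$loadings), integer(1))
  best <- max(abs(x$crossmodal_r))
  cat(sprintf(paste0("<pica_fit> %s: %d + %d components, %d epochs, %s\n",
                     "  max cross-modal loading |r| = %.3f; %d constrained pair(s)\n"),
              paste(names(x$modalities), collapse = " + "), k[1], k[2],
              nrow(x$log),
              if (x$converged) "converged" else "NOT converged",
              best, nrow(x$constrained_pairs)))
  invisible(x)
}
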