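#' Pipeline run configuration
#'
#' A single declarative config for the end-to-end analysis. Exactly one of
#' `simulate` (a [sim_config()]) or `inputs` (paths to NIfTI volumes, a mask
#' and a subject table) must be supplied. The method's standard constants —
#' 8 components, |z| > 2.5, FDR level 0.05, 5 folds, 8 mm smoothing for real
#' volumes — are defaults here, never hard-coded downstream.
#'
#' @param simulate A [sim_config()], or `NULL`.
#' @param inputs List with `paths1`, `paths2` (named NIfTI paths), `mask`
#'   (logical array or NIfTI path) and `subject_table` (data frame or TSV
#'   path), or `NULL`.
#' @param fwhm_mm Smoothing FWHM in mm; `NULL` skips smoothing (the default
#'   for simulated data, which is generated in template space).
#' @param normalize Apply SUVR-style intensity normalization (reference =
#'   whole analysis mask unless `reference_mask` is given).
#' @param reference_mask Optional reference-region mask for normalization.
#' @param n_components Integer, or `"auto"` to select by AIC per modality.
#' @param pica List of [pica_config()] overrides.
#' @param alpha Significance level for component tests and FDR.
#' @param z_cutoff Component-map |z| threshold.
#' @param atlas An [atlas_bundle()], a list of paths for [read_atlas()], or
#'   `NULL` to use a [synthetic_atlas()] on the analysis grid.
#' @param classify List: `k` (folds), `seed`, `refit_per_fold` (logical; the
#'   strict protocol refits the decomposition inside every training split).
#' @param output_dir Directory for stage outputs, or `NULL` to keep results
#'   in memory only.
#' @param seed Master seed; stage seeds derive from it.
#' @return List of class `run_config`.
#' @export
run_config <- function(simulate = NULL, inputs = NULL,
                       fwhm_mm = NULL, normalize = TRUE, reference_mask = NULL,
                       n_components = 8L, pica = list(),
                       alpha = 0.05, z_cutoff = 2.5, atlas = NULL,
                       classify = list(k = 5L, refit_per_fold = FALSE),
                       output_dir = NULL, seed = 1L) {
  if (is.null(simulate) == is.null(inputs)) {
    stopf("exactly one of `simulate` or `inputs` must be supplied.",
          class = "picafuse_config_error")
  }
  classify <- modifyList(list(k = 5L, refit_per_fold = FALSE), classify)
  structure(
    list(simulate = simulate, inputs = inputs, fwhm_mm = fwhm_mm,
         normalize = normalize, reference_mask = reference_mask,
         n_components = n_components, pica = pica, alpha = alpha,
         z_cutoff = z_cutoff, atlas = atlas, classify = classify,
         output_dir = output_dir, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Load a run configuration from YAML
#'
#' Thin reader for the CLI: the YAML keys mirror the [run_config()]
#' arguments, with `simulate` given as a map of [sim_config()] arguments.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) {
    y$simulate <- do.call(sim_config, y$simulate)
  }
  do.call(run_config, y)
}

stage_error <- function(stage, parent) {
  abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(parent)),
        class = c("picafuse_stage_error", "picafuse_error"),
        stage = stage, parent = parent)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — data (simulate or load), preprocess,
#' model order, parallel ICA, component statistics, atlas report,
#' classification — and returns every stage result together with a run
#' manifest (stage timings, config hash, seeds, package version). Reruns
#' with an identical config reproduce all outputs exactly.
#'
#' @param config A [run_config()].
#' @return List of class `pipeline_result`: `data`, `order`, `fit`, `stats`,
#'   `report`, `classification`, `manifest`, `files`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stages <- c("data", "preprocess", "order", "pica", "stats", "report", "classify")
  timings <- setNames(numeric(length(stages)), stages)
  files <- character(0)
  out_dir <- config$output_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  timed <- function(stage, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      if (inherits(e, "picafuse_stage_error")) stop(e)
      stage_error(stage, e)
    })
    timings[stage] <<- as.numeric(Sys.time() - t0, units = "secs")
    res
  }
  save_tsv <- function(df, name) {
    if (is.null(out_dir)) return(invisible(NULL))
    path <- file.path(out_dir, name)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, path)
  }

  # -- data ------------------------------------------------------------
  data <- timed("data", {
    if (!is.null(config$simulate)) {
      synthesize_dataset(config$simulate)
    } else {
      inp <- config$inputs
      mask <- if (is.character(inp$mask)) read_volume_nifti(inp$mask)$volume > 0 else inp$mask
      st <- if (is.character(inp$subject_table)) {
        read.delim(inp$subject_table, sep = "\t")
      } else {
        inp$subject_table
      }
      load_cohort(inp$paths1, inp$paths2, mask, st)
    }
  })
  vm1 <- data[[1]]
  vm2 <- data[[2]]
  subjects <- data$subjects
  labels <- factor(subjects$group)

  # -- preprocess ------------------------------------------------------
  pre <- timed("preprocess", {
    smooth_vm <- function(vm) {
      if (is.null(config$fwhm_mm)) return(vm)
      vox <- abs(diag(vm$affine)[1:3])
      sm <- t(apply(vm$values, 1L, function(row) {
        gaussian_smooth(unflatten(row, vm$mask), config$fwhm_mm, vox)[vm$mask]
      }))
      vm$values <- sm
      vm
    }
    vm1 <- smooth_vm(vm1)
    vm2 <- smooth_vm(vm2)
    if (config$normalize) {
      # SUVR scaling needs positive reference means; shift-invariant stages
      # follow, so skip with a message if intensities straddle zero
      ref_ok <- function(vm) {
        ref <- config$reference_mask %||% vm$mask
        all(rowMeans(vm$values[, which(ref[vm$mask]), drop = FALSE]) > 0)
      }
      if (ref_ok(vm1) && ref_ok(vm2)) {
        vm1 <- intensity_normalize(vm1, config$reference_mask)
        vm2 <- intensity_normalize(vm2, config$reference_mask)
      } else {
        message("skipping intensity normalization: nonpositive reference means.")
      }
    }
    list(vm1, vm2)
  })
  vm1 <- pre[[1]]
  vm2 <- pre[[2]]

  # -- model order -----------------------------------------------------
  order_stage <- timed("order", {
    if (identical(config$n_components, "auto")) {
      est <- list(estimate_order(vm1), estimate_order(vm2))
      list(estimates = est,
           k = c(est[[1]]$chosen_order, est[[2]]$chosen_order), mode = "auto")
    } else {
      list(estimates = NULL, k = rep(as.integer(config$n_components), 2L),
           mode = "fixed")
    }
  })

  # -- pICA ------------------------------------------------------------
  fit <- timed("pica", {
    pc <- do.call(pica_config, modifyList(
      list(n_components = order_stage$k, seed = child_seed(config$seed, 100L)),
      config$pica))
    parallel_ica(vm1, vm2, pc)
  })

  # -- statistics ------------------------------------------------------
  stats_stage <- timed("stats", {
    t1 <- loading_group_test(fit$modalities[[1]]$loadings, labels,
                             alpha = config$alpha, modality = vm1$modality)
    t2 <- loading_group_test(fit$modalities[[2]]$loadings, labels,
                             alpha = config$alpha, modality = vm2$modality)
    xmod <- crossmodal_correlations(fit$modalities[[1]]$loadings,
                                    fit$modalities[[2]]$loadings,
                                    alpha = config$alpha)
    cov_chk <- if (all(c("age", "sex") %in% names(subjects))) {
      covariate_check(fit$modalities[[1]]$loadings, subjects$age, subjects$sex)
    } else {
      NULL
    }
    cohort <- cohort_table(subjects)
    save_tsv(bind_rows(t1, t2), "component_tests.tsv")
    save_tsv(xmod, "crossmodal_correlations.tsv")
    save_tsv(cohort, "cohort_table.tsv")
    list(component_tests = bind_rows(t1, t2), crossmodal = xmod,
         covariates = cov_chk, cohort = cohort, tests1 = t1, tests2 = t2)
  })

  # -- atlas report ----------------------------------------------------
  report <- timed("report", {
    atlas <- config$atlas
    if (is.null(atlas)) atlas <- synthetic_atlas(dim(vm1$mask))
    if (is.list(atlas) && !inherits(atlas, "atlas_bundle")) {
      atlas <- do.call(read_atlas, atlas)
    }
    rep1 <- atlas_report(fit, stats_stage$tests1, atlas, 1L,
                         z_cutoff = config$z_cutoff)
    rep2 <- atlas_report(fit, stats_stage$tests2, atlas, 2L,
                         z_cutoff = config$z_cutoff)
    peaks <- bind_rows(
      rep1 |> mutate(modality = vm1$modality, .before = 1L),
      rep2 |> mutate(modality = vm2$modality, .before = 1L)
    )
    save_tsv(peaks, "peak_table.tsv")
    peaks
  })

  # -- classification --------------------------------------------------
  classification <- timed("classify", {
    cls_seed <- config$classify$seed %||% child_seed(config$seed, 200L)
    if (isTRUE(config$classify$refit_per_fold)) {
      reports <- refit_cross_validate(vm1, vm2, labels, config, cls_seed)
    } else {
      fts <- build_feature_tables(fit, vm1, vm2,
                                  stats_stage$tests1, stats_stage$tests2,
                                  z_cutoff = config$z_cutoff)
      reports <- map(fts, cross_validate, labels = labels,
                     k = config$classify$k, seed = cls_seed)
    }
    summary_tbl <- bind_rows(map(reports, glance))
    save_tsv(bind_rows(map(reports, tidy)), "classification_folds.tsv")
    if (!is.null(out_dir)) {
      path <- file.path(out_dir, "classification_summary.json")
      jsonlite::write_json(summary_tbl, path, auto_unbox = TRUE, digits = NA)
      files <- c(files, path)
    }
    list(reports = reports, summary = summary_tbl,
         protocol = if (isTRUE(config$classify$refit_per_fold)) {
           "decomposition refitted inside each training split"
         } else {
           "fixed components fitted once on the full panel"
         })
  })

  save_tsv(as.data.frame(fit$modalities[[1]]$loadings), "loadings_m1.tsv")
  save_tsv(as.data.frame(fit$modalities[[2]]$loadings), "loadings_m2.tsv")

  manifest <- list(
    package_version = as.character(packageVersion("picafuse")),
    config_hash = rlang::hash(config),
    seed = config$seed,
    stages = tibble(stage = stages, seconds = unname(timings[stages])),
    files = files,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  structure(
    list(data = data, order = order_stage, fit = fit, stats = stats_stage,
         report = report, classification = classification,
         manifest = manifest, files = files),
    class = "pipeline_result"
  )
}

# The strict cross-validation protocol: the decomposition, the component
# significance screen and the ROI masks are derived inside each training
# split, then frozen and applied to the held-out fold.
refit_cross_validate <- function(vm1, vm2, labels, config, seed) {
  k <- config$classify$k
  folds <- stratified_kfold(labels, k = k, seed = seed)
  conditions <- c("Non", "Tau", "Abeta", "All")
  per_fold <- map(seq_len(k), function(f) {
    tr <- folds != f
    sub_vm <- function(vm, keep) {
      voxel_matrix(vm$values[keep, , drop = FALSE], vm$mask, vm$affine,
                   subject_ids = vm$subject_ids[keep], modality = vm$modality)
    }
    pc <- do.call(pica_config, modifyList(
      list(n_components = rep(as.integer(
        if (identical(config$n_components, "auto")) 8L else config$n_components), 2L),
        seed = child_seed(seed, f)),
      config$pica))
    fit_tr <- suppressWarnings(parallel_ica(sub_vm(vm1, tr), sub_vm(vm2, tr), pc))
    t1 <- loading_group_test(fit_tr$modalities[[1]]$loadings, labels[tr],
                             alpha = config$alpha, modality = vm1$modality)
    t2 <- loading_group_test(fit_tr$modalities[[2]]$loadings, labels[tr],
                             alpha = config$alpha, modality = vm2$modality)
    # fall back to the strongest component when a split finds none significant
    if (!any(t1$significant)) t1$significant[which.min(t1$p)] <- TRUE
    if (!any(t2$significant)) t2$significant[which.min(t2$p)] <- TRUE
    fts <- build_feature_tables(fit_tr, vm1, vm2, t1, t2,
                                z_cutoff = config$z_cutoff)
    map(fts, function(ft) {
      x <- as.matrix(ft[setdiff(names(ft), "subject_id")])
      scorer <- fit_linear_classifier(x[tr, , drop = FALSE], labels[tr], "MCI")
      sc <- scorer(x[!tr, , drop = FALSE])
      truth <- labels[!tr] == "MCI"
      pred <- sc > 0
      tibble(fold = f,
             acc = 100 * mean(pred == truth),
             auc = 100 * roc_auc(sc, labels[!tr], positive = "MCI"),
             sen = 100 * mean(pred[truth]),
             spe = 100 * mean(!pred[!truth]))
    })
  })
  map(setNames(conditions, conditions), function(cond) {
    folds_tbl <- bind_rows(map(per_fold, `[[`, cond))
    structure(
      list(folds = folds_tbl,
           mean = summarise(folds_tbl, across(c("acc", "auc", "sen", "spe"), mean)),
           condition = cond, fold_assignment = folds,
           scores = NULL, labels = labels, positive = "MCI",
           classifier = "L2-penalised logistic regression (refit-per-fold protocol)",
           seed = seed),
      class = "classification_report"
    )
  })
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$manifest$stages)
  invisible(x)
}
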