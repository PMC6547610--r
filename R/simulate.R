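#' Configuration for the paired-modality simulator
#'
#' Defines the study conditions the simulator emulates: a two-group cohort
#' (default 65 MCI / 75 NC) scanned with two modalities that share a voxel
#' grid, a small number of latent spatial sources per modality (default 8),
#' one cross-modal pair of loading columns coupled at a target correlation
#' (default 0.6, the magnitude of the strongest coupling the method is meant
#' to recover), a subset of components whose loadings differ between groups,
#' and additive Gaussian voxel noise.
#'
#' @param grid_dims Three positive integers: voxels per axis. The default
#'   20 x 24 x 20 at 4 mm is small enough for desk-scale runs yet leaves room
#'   for eight separable blob sources inside the ellipsoid mask.
#' @param n_subjects_per_group Two positive integers, sizes of the MCI and NC
#'   groups.
#' @param n_components Number of latent spatial sources per modality.
#' @param coupled_pair Integer pair `(i, j)`: component `i` of modality 1 is
#'   coupled to component `j` of modality 2.
#' @param coupled_r Target population correlation of the coupled loading
#'   columns, in (-1, 1).
#' @param group_effect_components List with elements `m1` and `m2`: component
#'   indices (per modality) whose loadings receive a group mean shift.
#' @param group_effect_size Cohen's d of the shift applied to each flagged
#'   component (MCI minus NC, in units of the unit loading SD).
#' @param noise_sd Standard deviation of the additive Gaussian voxel noise.
#' @param blob_count_range Integer range: Gaussian blobs per source.
#' @param blob_fwhm_mm Full-width-at-half-maximum of each blob, in mm.
#' @param voxel_size_mm Isotropic voxel edge length in mm.
#' @param modality_names Two strings naming the modalities.
#' @param seed Integer seed; the generator is a pure function of the config.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(grid_dims = c(20L, 24L, 20L),
                       n_subjects_per_group = c(65L, 75L),
                       n_components = 8L,
                       coupled_pair = c(1L, 1L),
                       coupled_r = 0.6,
                       group_effect_components = list(m1 = c(2L, 3L), m2 = c(4L, 5L)),
                       group_effect_size = 0.8,
                       noise_sd = 0.1,
                       blob_count_range = c(2L, 4L),
                       blob_fwhm_mm = 12,
                       voxel_size_mm = 4,
                       modality_names = c("tau", "abeta"),
                       seed = 1L) {
  cfg <- list(
    grid_dims = as.integer(grid_dims),
    n_subjects_per_group = as.integer(n_subjects_per_group),
    n_components = as.integer(n_components),
    coupled_pair = as.integer(coupled_pair),
    coupled_r = coupled_r,
    group_effect_components = lapply(group_effect_components, as.integer),
    group_effect_size = group_effect_size,
    noise_sd = noise_sd,
    blob_count_range = as.integer(blob_count_range),
    blob_fwhm_mm = blob_fwhm_mm,
    voxel_size_mm = voxel_size_mm,
    modality_names = as.character(modality_names),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (length(cfg$grid_dims) != 3L || any(cfg$grid_dims < 1L)) {
    stopf("`grid_dims` must be 3 positive integers.", class = "picafuse_domain_error")
  }
  if (length(cfg$n_subjects_per_group) != 2L || any(cfg$n_subjects_per_group < 1L)) {
    stopf("`n_subjects_per_group` must be 2 positive integers.",
          class = "picafuse_domain_error")
  }
  if (cfg$n_components < 1L) {
    stopf("`n_components` must be positive.", class = "picafuse_domain_error")
  }
  if (any(cfg$coupled_pair < 1L) || any(cfg$coupled_pair > cfg$n_components)) {
    stopf("`coupled_pair` indices must lie in 1..n_components.",
          class = "picafuse_domain_error")
  }
  if (abs(cfg$coupled_r) >= 1) {
    stopf("`coupled_r` must lie strictly inside (-1, 1).",
          class = "picafuse_domain_error")
  }
  if (cfg$noise_sd < 0) {
    stopf("`noise_sd` must be nonnegative.", class = "picafuse_domain_error")
  }
  bad <- unlist(cfg$group_effect_components)
  if (length(bad) && (any(bad < 1L) || any(bad > cfg$n_components))) {
    stopf("`group_effect_components` indices must lie in 1..n_components.",
          class = "picafuse_domain_error")
  }
  # identifiability head-room: enough in-mask voxels per source
  if (prod(cfg$grid_dims) < cfg$n_components * 50) {
    stopf(paste("grid volume %d is below the identifiability floor of",
                "n_components x 50 = %d voxels."),
          prod(cfg$grid_dims), cfg$n_components * 50,
          class = "picafuse_identifiability_error")
  }
  invisible(cfg)
}

# Evaluate a 3-D Gaussian blob over the grid (in voxel units).
blob_field <- function(grid_dims, centre, sigma_vox) {
  dx <- (seq_len(grid_dims[1]) - centre[1])^2
  dy <- (seq_len(grid_dims[2]) - centre[2])^2
  dz <- (seq_len(grid_dims[3]) - centre[3])^2
  ex <- exp(-dx / (2 * sigma_vox^2))
  ey <- exp(-dy / (2 * sigma_vox^2))
  ez <- exp(-dz / (2 * sigma_vox^2))
  outer(outer(ex, ey), ez)
}

#' Generate spatial source maps for one modality
#'
#' Each source is a sum of positive 3-D Gaussian blobs at distinct random
#' in-mask centres, standardised to zero mean and unit (sample) variance over
#' the mask. Sources are accepted only if their absolute spatial correlation
#' with every previously placed source stays at or below 0.3, which keeps the
#' latent maps close to orthogonal and identifiable; placement is retried a
#' bounded number of times and an identifiability error is raised when the
#' grid cannot host that many separated sources.
#'
#' The positive-blob construction makes each map spatially sparse and
#' right-skewed (super-Gaussian over voxels), the regime the infomax engine's
#' logistic nonlinearity separates.
#'
#' @param config A [sim_config()].
#' @param modality Which modality's sources to draw (1 or 2); the two
#'   modalities use independent substreams of `config$seed`.
#' @return List: `maps` (components x in-mask-voxels matrix), `mask`,
#'   `centres` (list of blob-centre matrices), `affine`.
#' @export
generate_source_maps <- function(config, modality = 1L) {
  mask <- ellipsoid_mask(config$grid_dims)
  mask_idx <- which(mask)
  coords <- arrayInd(mask_idx, config$grid_dims)
  sigma_vox <- config$blob_fwhm_mm / (2 * sqrt(2 * log(2))) / config$voxel_size_mm
  min_sep_vox <- config$blob_fwhm_mm / config$voxel_size_mm
  k <- config$n_components

  with_seed(child_seed(config$seed, 10L + modality), {
    maps <- matrix(0, k, length(mask_idx))
    centres <- vector("list", k)
    for (comp in seq_len(k)) {
      placed <- FALSE
      for (attempt in seq_len(200L)) {
        n_blob <- sample(seq(config$blob_count_range[1], config$blob_count_range[2]), 1L)
        pick <- coords[sample(nrow(coords), n_blob), , drop = FALSE]
        amp <- runif(n_blob, 0.5, 1)
        vol <- array(0, config$grid_dims)
        for (b in seq_len(n_blob)) {
          vol <- vol + amp[b] * blob_field(config$grid_dims, pick[b, ], sigma_vox)
        }
        v <- vol[mask]
        v <- (v - mean(v)) / sd(v)
        ok <- TRUE
        if (comp > 1L) {
          r <- abs(as.vector(cor(v, t(maps[seq_len(comp - 1L), , drop = FALSE]))))
          ok <- all(r <= 0.3)
        }
        if (ok) {
          maps[comp, ] <- v
          centres[[comp]] <- pick
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stopf(paste("could not place source %d with pairwise |spatial",
                    "correlation| <= 0.3 on a %s grid; the grid is too small",
                    "for %d separable sources."),
              comp, paste(config$grid_dims, collapse = "x"), k,
              class = "picafuse_identifiability_error")
      }
    }
    list(maps = maps, mask = mask, centres = centres,
         affine = grid_affine(config$grid_dims, config$voxel_size_mm))
  })
}

#' Generate coupled, group-shifted loading matrices
#'
#' Loadings are standard Gaussian per component. The configured cross-modal
#' pair is drawn jointly from a bivariate Gaussian so its population
#' correlation equals `coupled_r` (all other cross-modal column pairs are
#' independent), and each flagged component's loadings receive a group mean
#' shift of `group_effect_size` standard deviations (MCI minus NC). The
#' realised coupled-pair correlation and per-component realised effect sizes
#' are recorded in the returned truth object.
#'
#' @param config A [sim_config()].
#' @return List with `A1`, `A2` (subjects x components matrices) and `truth`,
#'   a `synthetic_truth` object carrying group labels, the realised coupling
#'   and an effect-size table.
#' @export
generate_loadings <- function(config) {
  n1 <- config$n_subjects_per_group[1]
  n2 <- config$n_subjects_per_group[2]
  n <- n1 + n2
  k <- config$n_components
  groups <- factor(rep(c("MCI", "NC"), c(n1, n2)), levels = c("MCI", "NC"))
  subject_ids <- sprintf("S%03d", seq_len(n))

  with_seed(child_seed(config$seed, 20L), {
    A1 <- matrix(rnorm(n * k), n, k)
    A2 <- matrix(rnorm(n * k), n, k)
    i <- config$coupled_pair[1]
    j <- config$coupled_pair[2]
    rho <- config$coupled_r
    # bivariate Gaussian: col j of A2 rebuilt from col i of A1 plus noise
    A2[, j] <- rho * A1[, i] + sqrt(1 - rho^2) * rnorm(n)
    shift <- ifelse(groups == "MCI", config$group_effect_size, 0)
    for (comp in config$group_effect_components$m1) A1[, comp] <- A1[, comp] + shift
    for (comp in config$group_effect_components$m2) A2[, comp] <- A2[, comp] + shift
    colnames(A1) <- sprintf("C%d", seq_len(k))
    colnames(A2) <- sprintf("C%d", seq_len(k))
    rownames(A1) <- rownames(A2) <- subject_ids

    cohens_d <- function(col) {
      x <- col[groups == "MCI"]; y <- col[groups == "NC"]
      sp <- sqrt(((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n - 2))
      (mean(x) - mean(y)) / sp
    }
    effect_table <- bind_rows(
      tibble(modality = 1L, component = seq_len(k),
             true_d = ifelse(seq_len(k) %in% config$group_effect_components$m1,
                             config$group_effect_size, 0),
             realized_d = apply(A1, 2L, cohens_d)),
      tibble(modality = 2L, component = seq_len(k),
             true_d = ifelse(seq_len(k) %in% config$group_effect_components$m2,
                             config$group_effect_size, 0),
             realized_d = apply(A2, 2L, cohens_d))
    )
    truth <- structure(
      list(loadings = list(A1, A2),
           sources = NULL,  # filled by synthesize_dataset()
           coupled_pair = config$coupled_pair,
           coupled_r_target = rho,
           coupled_r_realized = cor(A1[, i], A2[, j]),
           group_labels = setNames(groups, subject_ids),
           effect_table = effect_table,
           config = config),
      class = "synthetic_truth"
    )
    list(A1 = A1, A2 = A2, truth = truth)
  })
}

#' Synthesize a paired-modality dataset
#'
#' Builds `X_m = A_m S_m + E_m` for both modalities: spatial sources from
#' [generate_source_maps()], loadings from [generate_loadings()], and i.i.d.
#' Gaussian voxel noise with standard deviation `noise_sd`. Identical configs
#' (including seed) produce bit-identical datasets.
#'
#' @param config A [sim_config()].
#' @return List with one [voxel_matrix()] per modality (named after
#'   `config$modality_names`), the `truth` object (now carrying the sources),
#'   and a simulated `subjects` table.
#' @export
synthesize_dataset <- function(config) {
  src1 <- generate_source_maps(config, modality = 1L)
  src2 <- generate_source_maps(config, modality = 2L)
  ld <- generate_loadings(config)
  n <- sum(config$n_subjects_per_group)

  noise <- with_seed(child_seed(config$seed, 30L), {
    list(matrix(rnorm(n * ncol(src1$maps), sd = config$noise_sd), n, ncol(src1$maps)),
         matrix(rnorm(n * ncol(src2$maps), sd = config$noise_sd), n, ncol(src2$maps)))
  })
  X1 <- ld$A1 %*% src1$maps + noise[[1]]
  X2 <- ld$A2 %*% src2$maps + noise[[2]]

  truth <- ld$truth
  truth$sources <- list(src1$maps, src2$maps)
  truth$mask <- src1$mask
  truth$affine <- src1$affine

  subjects <- simulate_subject_table(config, truth$group_labels)

  out <- list(
    voxel_matrix(X1, src1$mask, src1$affine,
                 subject_ids = rownames(ld$A1), modality = config$modality_names[1]),
    voxel_matrix(X2, src2$mask, src2$affine,
                 subject_ids = rownames(ld$A2), modality = config$modality_names[2]),
    truth = truth, subjects = subjects
  )
  names(out)[1:2] <- config$modality_names
  out
}

# Cohort table emulating the demographics of a 65 MCI / 75 NC tau+amyloid
# study population (ages in the mid 70s, MCI MMSE ~25.7 vs NC ~27.9, CDR 0.5
# vs 0, near-balanced sex and APOE4 carriage).
simulate_subject_table <- function(config, group_labels) {
  n <- length(group_labels)
  with_seed(child_seed(config$seed, 40L), {
    mci <- group_labels == "MCI"
    tibble(
      subject_id = names(group_labels),
      group = as.character(group_labels),
      age = round(ifelse(mci, rnorm(n, 73.3, 5.8), rnorm(n, 76.3, 6.2)), 1),
      sex = sample(c("M", "F"), n, replace = TRUE),
      apoe4 = rbinom(n, 1L, ifelse(mci, 0.49, 0.44)),
      mmse = pmin(30L, round(ifelse(mci, rnorm(n, 25.7, 2.3), rnorm(n, 27.9, 1.7)))),
      cdr = ifelse(mci, 0.5, 0)
    )
  })
}

#' Export a simulated dataset to disk
#'
#' Writes one NIfTI-1 volume per subject per modality
#' (`<modality>_<subjectID>.nii.gz`), the subject table as TSV, and the
#' ground truth (loadings, coupled pair, effect table) as JSON.
#'
#' @param dataset Result of [synthesize_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a character vector of the files written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- dataset$truth
  files <- character(0)
  for (m in 1:2) {
    vm <- dataset[[m]]
    for (s in seq_along(vm$subject_ids)) {
      path <- file.path(dir, sprintf("%s_%s.nii.gz", vm$modality, vm$subject_ids[s]))
      write_volume_nifti(unflatten(vm$values[s, ], vm$mask), vm$affine, path)
      files <- c(files, path)
    }
  }
  tsv <- file.path(dir, "subjects.tsv")
  write.table(dataset$subjects, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  truth_json <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(coupled_pair = truth$coupled_pair,
         coupled_r_target = truth$coupled_r_target,
         coupled_r_realized = truth$coupled_r_realized,
         group_labels = as.character(truth$group_labels),
         effect_table = truth$effect_table,
         loadings = lapply(truth$loadings, unname)),
    truth_json, auto_unbox = TRUE, digits = NA)
  invisible(c(files, tsv, truth_json))
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_truth> %d subjects (%s), %d components/modality\n",
                     "  coupled pair (%d, %d): target r = %.3f, realized r = %.3f\n"),
              length(x$group_labels),
              paste(table(x$group_labels), collapse = "/"),
              x$config$n_components,
              x$coupled_pair[1], x$coupled_pair[2],
              x$coupled_r_target, x$coupled_r_realized))
  invisible(x)
}
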