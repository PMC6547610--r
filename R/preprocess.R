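#' Separable 3-D Gaussian smoothing
#'
#' Convolves a volume with a separable Gaussian kernel specified by its
#' full-width-at-half-maximum in mm, the convention PET pipelines use to bring
#' scans to a uniform effective resolution (8 mm FWHM being the usual target).
#' Per axis, `sigma = fwhm_mm / (2 sqrt(2 ln 2)) / voxel_size`. The 1-D kernel
#' is sampled out to four sigma and normalised to unit sum, so constant
#' volumes pass through unchanged; boundaries are handled by nearest-edge
#' replication.
#'
#' @param volume 3-D numeric array.
#' @param fwhm_mm Positive scalar kernel FWHM in mm.
#' @param voxel_size_mm Voxel edge lengths in mm (length 1 or 3).
#' @return Smoothed 3-D array of the same dimensions.
#' @export
gaussian_smooth <- function(volume, fwhm_mm, voxel_size_mm) {
  check_positive_scalar(fwhm_mm, "fwhm_mm")
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0)) {
    stopf("`voxel_size_mm` must be 1 or 3 positive values.",
          class = "picafuse_domain_error")
  }
  if (length(dim(volume)) != 3L) {
    stopf("`volume` must be a 3-D array.", class = "picafuse_domain_error")
  }
  out <- volume
  for (axis in 1:3) {
    sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm[axis]
    out <- smooth_axis(out, gaussian_kernel_1d(sigma), axis)
  }
  out
}

# Unit-sum 1-D Gaussian kernel sampled at integer offsets out to 4 sigma.
gaussian_kernel_1d <- function(sigma) {
  radius <- max(1L, ceiling(4 * sigma))
  offsets <- seq.int(-radius, radius)
  k <- exp(-offsets^2 / (2 * sigma^2))
  k / sum(k)
}

# Convolve along one axis with nearest-edge replication.
smooth_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  n <- d[axis]
  radius <- (length(kernel) - 1L) / 2L
  out <- array(0, d)
  for (t in seq_along(kernel)) {
    offset <- t - radius - 1L
    idx <- pmin(pmax(seq_len(n) + offset, 1L), n)
    shifted <- switch(axis,
                      arr[idx, , , drop = FALSE],
                      arr[, idx, , drop = FALSE],
                      arr[, , idx, drop = FALSE])
    out <- out + kernel[t] * shifted
  }
  out
}

#' SUVR-style intensity normalization
#'
#' Divides each subject's row by that subject's mean over a reference region,
#' removing global intensity differences between scans. The reference region
#' is an explicit mask (PET pipelines variously use cerebellum, pons, or the
#' whole analysis support); the default is the whole analysis mask, under
#' which every subject's row mean becomes exactly 1.
#'
#' @param vm A [voxel_matrix()].
#' @param reference_mask Logical 3-D array, a subset of `vm$mask`; `NULL`
#'   means the whole analysis mask.
#' @return A [voxel_matrix()] with scaled rows.
#' @export
intensity_normalize <- function(vm, reference_mask = NULL) {
  stopifnot(inherits(vm, "voxel_matrix"))
  if (is.null(reference_mask)) reference_mask <- vm$mask
  if (!identical(dim(reference_mask), dim(vm$mask))) {
    stopf("reference mask grid differs from the analysis mask grid.",
          class = "picafuse_domain_error")
  }
  if (any(reference_mask & !vm$mask)) {
    stopf("reference mask extends outside the analysis mask.",
          class = "picafuse_domain_error")
  }
  ref_cols <- which(reference_mask[vm$mask])
  if (length(ref_cols) == 0L) {
    stopf("reference mask is empty.", class = "picafuse_domain_error")
  }
  ref_mean <- unname(rowMeans(vm$values[, ref_cols, drop = FALSE]))
  bad <- which(ref_mean <= 0)
  if (length(bad)) {
    stopf("nonpositive reference mean for subject(s): %s",
          paste(vm$subject_ids[bad], collapse = ", "),
          class = "picafuse_domain_error")
  }
  vm$values <- vm$values / ref_mean
  vm
}

#' Load a paired two-modality cohort from NIfTI volumes
#'
#' Reads per-subject volumes for two modalities, checks that every volume
#' shares the grid and affine (within 1e-4) and that every subject is present
#' in both modalities, applies the analysis mask, and drops voxels with zero
#' variance across subjects (they carry no between-subject signal and break
#' whitening); the dropped count is reported via `message()`.
#'
#' @param paths1,paths2 Named character vectors of NIfTI paths, one per
#'   subject, names = subject ids, for modalities 1 and 2.
#' @param mask Logical 3-D array; the analysis support.
#' @param subject_table Data frame with at least `subject_id` and `group`;
#'   its row order fixes the subject order of both matrices.
#' @param modalities Two modality tags.
#' @return List of two [voxel_matrix()] objects plus the subject table.
#' @export
load_cohort <- function(paths1, paths2, mask, subject_table,
                        modalities = c("tau", "abeta")) {
  ids <- subject_table$subject_id
  for (nm in list(paths1, paths2)) {
    missing_ids <- setdiff(ids, names(nm))
    if (length(missing_ids)) {
      stopf("subject(s) missing from one modality: %s",
            paste(missing_ids, collapse = ", "),
            class = "picafuse_pairing_error")
    }
  }
  read_modality <- function(paths, modality) {
    ref <- NULL
    rows <- matrix(NA_real_, length(ids), sum(mask))
    for (s in seq_along(ids)) {
      nif <- read_volume_nifti(paths[[ids[s]]])
      if (!identical(dim(nif$volume), dim(mask))) {
        stopf("grid of '%s' (%s) does not match the mask grid (%s).",
              paths[[ids[s]]], paste(dim(nif$volume), collapse = "x"),
              paste(dim(mask), collapse = "x"),
              class = "picafuse_grid_error")
      }
      if (is.null(ref)) {
        ref <- nif$affine
      } else if (max(abs(nif$affine - ref)) > 1e-4) {
        stopf("affine of '%s' differs from the first volume by more than 1e-4.",
              paths[[ids[s]]], class = "picafuse_grid_error")
      }
      rows[s, ] <- nif$volume[mask]
    }
    list(values = rows, affine = ref)
  }
  m1 <- read_modality(paths1, modalities[1])
  m2 <- read_modality(paths2, modalities[2])
  if (max(abs(m1$affine - m2$affine)) > 1e-4) {
    stopf("modality affines differ by more than 1e-4.",
          class = "picafuse_grid_error")
  }

  keep <- col_sds(m1$values) > 0 & col_sds(m2$values) > 0
  if (any(!keep)) {
    message(sprintf("dropping %d zero-variance voxel(s) from the mask.", sum(!keep)))
    mask_idx <- which(mask)
    mask[mask_idx[!keep]] <- FALSE
    m1$values <- m1$values[, keep, drop = FALSE]
    m2$values <- m2$values[, keep, drop = FALSE]
  }
  out <- list(
    voxel_matrix(m1$values, mask, m1$affine, subject_ids = ids, modality = modalities[1]),
    voxel_matrix(m2$values, mask, m2$affine, subject_ids = ids, modality = modalities[2]),
    subjects = as_tibble(subject_table)
  )
  names(out)[1:2] <- modalities
  out
}
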