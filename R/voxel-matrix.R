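#' Subjects-by-voxels matrix with volumetric metadata
#'
#' `voxel_matrix()` bundles a flattened subjects x in-mask-voxels data matrix
#' with the boolean 3-D mask it was flattened under, the voxel-to-mm affine,
#' subject identifiers and a modality tag. It is the per-modality container
#' every downstream stage (model-order selection, the pICA engine, voxel-wise
#' statistics, feature extraction) consumes.
#'
#' Columns of `values` correspond, in order, to `which(mask)` — column-major
#' traversal of the `TRUE` voxels. Voxel indices are 0-based when converted to
#' mm through the affine (RAS+ convention).
#'
#' @param values Numeric matrix, subjects x in-mask voxels.
#' @param mask Logical 3-D array; `sum(mask)` must equal `ncol(values)`.
#' @param affine 4x4 numeric voxel-index-to-mm transform.
#' @param subject_ids Character vector of row identifiers.
#' @param modality Single string tag (e.g. `"tau"`, `"abeta"`).
#' @return An object of class `voxel_matrix`.
#' @export
voxel_matrix <- function(values, mask, affine = diag(4), subject_ids = NULL,
                         modality = "unknown") {
  values <- as.matrix(values)
  if (!is.array(mask) || length(dim(mask)) != 3L || !is.logical(mask)) {
    stopf("`mask` must be a logical 3-D array.", class = "picafuse_domain_error")
  }
  if (sum(mask) != ncol(values)) {
    stopf("mask has %d TRUE voxels but `values` has %d columns.",
          sum(mask), ncol(values), class = "picafuse_domain_error")
  }
  if (!identical(dim(affine), c(4L, 4L))) {
    stopf("`affine` must be a 4x4 matrix.", class = "picafuse_domain_error")
  }
  if (any(!is.finite(values))) {
    stopf("`values` contains non-finite entries.", class = "picafuse_domain_error")
  }
  if (is.null(subject_ids)) {
    subject_ids <- rownames(values) %||% sprintf("S%03d", seq_len(nrow(values)))
  }
  if (length(subject_ids) != nrow(values)) {
    stopf("%d subject ids for %d rows.", length(subject_ids), nrow(values),
          class = "picafuse_domain_error")
  }
  rownames(values) <- subject_ids
  structure(
    list(values = values, mask = mask, affine = affine,
         subject_ids = subject_ids, modality = modality),
    class = "voxel_matrix"
  )
}

#' @export
print.voxel_matrix <- function(x, ...) {
  cat(sprintf("<voxel_matrix> %s: %d subjects x %d in-mask voxels (grid %s)\n",
              x$modality, nrow(x$values), ncol(x$values),
              paste(dim(x$mask), collapse = "x")))
  invisible(x)
}

#' @export
dim.voxel_matrix <- function(x) dim(x$values)

#' Ellipsoid analysis mask
#'
#' Brain-like support for simulated volumes: all voxels inside the ellipsoid
#' inscribed in the grid box.
#'
#' @param grid_dims Integer vector of three grid dimensions.
#' @return Logical 3-D array.
#' @export
ellipsoid_mask <- function(grid_dims) {
  stopifnot(length(grid_dims) == 3L, all(grid_dims >= 1))
  centre <- (grid_dims + 1) / 2
  radii <- grid_dims / 2
  i <- slice.index(array(0, grid_dims), 1L)
  j <- slice.index(array(0, grid_dims), 2L)
  k <- slice.index(array(0, grid_dims), 3L)
  ((i - centre[1]) / radii[1])^2 + ((j - centre[2]) / radii[2])^2 +
    ((k - centre[3]) / radii[3])^2 <= 1
}

#' Re-inflate a flattened in-mask vector to a 3-D volume
#'
#' @param x Numeric vector with one entry per `TRUE` mask voxel.
#' @param mask Logical 3-D array.
#' @param fill Value for out-of-mask voxels (default 0).
#' @return 3-D numeric array with `dim(mask)`.
#' @export
unflatten <- function(x, mask, fill = 0) {
  if (length(x) != sum(mask)) {
    stopf("vector length %d does not match mask voxel count %d.",
          length(x), sum(mask), class = "picafuse_domain_error")
  }
  vol <- array(fill, dim(mask))
  vol[mask] <- x
  vol
}

#' Flatten a 3-D volume to its in-mask vector
#'
#' @param volume 3-D numeric array.
#' @param mask Logical 3-D array of the same dimensions.
#' @return Numeric vector of `volume[mask]` in column-major mask order.
#' @export
flatten_volume <- function(volume, mask) {
  if (!identical(dim(volume), dim(mask))) {
    stopf("volume and mask dimensions differ.", class = "picafuse_domain_error")
  }
  volume[mask]
}

# Default affine for a simulated grid: isotropic spacing, mm origin placed so
# the grid centre sits at (0, 0, 0).
grid_affine <- function(grid_dims, voxel_size_mm) {
  aff <- diag(c(rep(voxel_size_mm, 3), 1))
  aff[1:3, 4] <- -voxel_size_mm * (grid_dims - 1) / 2
  aff
}

# Write one 3-D volume as NIfTI-1 with the given affine.
write_volume_nifti <- function(volume, affine, path, voxel_size_mm = NULL) {
  img <- RNifti::asNifti(volume)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  list(volume = as.array(img), affine = unclass(RNifti::xform(img)))
}
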