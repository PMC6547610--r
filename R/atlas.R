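#' Supra-threshold clusters and their peaks
#'
#' Finds the connected components of `|z| > threshold` (strict) under 6-, 18-
#' or 26-neighbour connectivity and reports each cluster's size and peak: the
#' voxel of maximum |z|, ties broken toward the lowest linear (column-major)
#' voxel index. Labelling is a two-pass union-find sweep over the
#' half-neighbourhood.
#'
#' @param zmap 3-D numeric array of z values.
#' @param threshold Positive cluster-forming threshold (default 2.5).
#' @param connectivity 6, 18 or 26 (default 26).
#' @return Tibble: `cluster`, `n_voxels`, `peak_z` (signed z at the peak),
#'   `peak_abs_z`, `i`, `j`, `k` (0-based voxel indices of the peak).
#' @export
find_peaks <- function(zmap, threshold = 2.5, connectivity = 26L) {
  check_positive_scalar(threshold, "threshold")
  if (!connectivity %in% c(6L, 18L, 26L)) {
    stopf("`connectivity` must be 6, 18 or 26.", class = "picafuse_domain_error")
  }
  if (length(dim(zmap)) != 3L) {
    stopf("`zmap` must be a 3-D array.", class = "picafuse_domain_error")
  }
  labels <- label_clusters(abs(zmap) > threshold, connectivity)
  n_clust <- max(labels)
  if (n_clust == 0L) {
    return(tibble(cluster = integer(0), n_voxels = integer(0),
                  peak_z = numeric(0), peak_abs_z = numeric(0),
                  i = integer(0), j = integer(0), k = integer(0)))
  }
  idx <- which(labels > 0L)
  lab <- labels[idx]
  absz <- abs(zmap[idx])
  rows <- map(seq_len(n_clust), function(cl) {
    members <- idx[lab == cl]
    vals <- absz[lab == cl]
    peak_lin <- min(members[vals == max(vals)])  # lowest linear index wins ties
    ijk <- arrayInd(peak_lin, dim(zmap)) - 1L
    tibble(cluster = cl, n_voxels = length(members),
           peak_z = zmap[peak_lin], peak_abs_z = abs(zmap[peak_lin]),
           i = ijk[1], j = ijk[2], k = ijk[3])
  })
  bind_rows(rows) |> arrange(dplyr::desc(.data$peak_abs_z))
}

# Neighbour offsets for a connectivity class (half-neighbourhood comes from
# taking the lexicographically negative half).
connectivity_offsets <- function(connectivity) {
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  degree <- rowSums(abs(offs))
  keep <- switch(as.character(connectivity),
                 "6" = degree == 1, "18" = degree <= 2, "26" = degree <= 3)
  offs[keep, , drop = FALSE]
}

# Connected-component labelling of a logical 3-D array via union-find.
label_clusters <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  n <- prod(d)
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  offs <- connectivity_offsets(connectivity)
  # half neighbourhood: strictly "earlier" in column-major order
  half <- offs[offs[, 3] < 0 |
                 (offs[, 3] == 0 & offs[, 2] < 0) |
                 (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] < 0), , drop = FALSE]
  idx <- which(mask)
  if (!length(idx)) return(array(0L, d))
  coord <- arrayInd(idx, d)
  for (t in seq_len(nrow(half))) {
    nb <- coord + matrix(half[t, ], nrow(coord), 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb_lin <- (nb[ok, 3] - 1L) * d[1] * d[2] + (nb[ok, 2] - 1L) * d[1] + nb[ok, 1]
    cur <- idx[ok]
    inside <- mask[nb_lin]
    for (s in which(inside)) {
      ra <- find(cur[s]); rb <- find(nb_lin[s])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(idx, find, integer(1))
  labels <- array(0L, d)
  labels[idx] <- as.integer(factor(roots))
  labels
}

#' Voxel indices to mm coordinates
#'
#' Homogeneous transform of 0-based voxel indices through a NIfTI-style
#' affine (RAS+ mm on output).
#'
#' @param voxels Integer vector of length 3 or an n x 3 matrix of 0-based
#'   voxel indices.
#' @param affine 4x4 invertible voxel-to-mm transform.
#' @return Numeric vector/matrix of mm coordinates.
#' @export
voxel_to_mm <- function(voxels, affine) {
  if (abs(det(affine)) < .Machine$double.eps) {
    stopf("affine is singular.", class = "picafuse_domain_error")
  }
  vector_in <- !is.matrix(voxels)
  v <- rbind(t(matrix(as.numeric(voxels), ncol = 3)), 1)
  out <- t(affine %*% v)[, 1:3, drop = FALSE]
  if (vector_in && length(voxels) == 3L) as.numeric(out) else out
}

#' Bundle an atlas label volume with its lookup tables
#'
#' @param label_volume Integer-valued 3-D array on the analysis grid.
#' @param label_table Data frame: `label_id`, `region_name`.
#' @param network_map Data frame: `region_name`, `network`.
#' @return List of class `atlas_bundle`.
#' @export
atlas_bundle <- function(label_volume, label_table, network_map) {
  used <- setdiff(unique(as.vector(label_volume)), 0)
  missing_lab <- setdiff(used, label_table$label_id)
  if (length(missing_lab)) {
    stopf("label volume values missing from the label table: %s",
          paste(missing_lab, collapse = ", "), class = "picafuse_domain_error")
  }
  structure(list(label_volume = label_volume,
                 label_table = as_tibble(label_table),
                 network_map = as_tibble(network_map)),
            class = "atlas_bundle")
}

#' Read an atlas from NIfTI + TSV files
#'
#' @param label_nifti Path to an integer-valued NIfTI label volume.
#' @param label_tsv TSV with columns `label_id`, `region_name`.
#' @param network_tsv TSV with columns `region_name`, `network`.
#' @return An [atlas_bundle()].
#' @export
read_atlas <- function(label_nifti, label_tsv, network_tsv) {
  vol <- read_volume_nifti(label_nifti)$volume
  atlas_bundle(round(vol),
               read.delim(label_tsv, sep = "\t"),
               read.delim(network_tsv, sep = "\t"))
}

#' Attach region and network labels to cluster peaks
#'
#' Looks up each peak voxel in the atlas label volume (label 0 maps to
#' `"unassigned"`), joins the region's network, converts the peak to mm
#' through the affine, and carries the component-level p-value when the
#' component tests are supplied — producing rows shaped like a published
#' peak table (region | |z| | network | component p | X Y Z).
#'
#' @param peaks Tibble from [find_peaks()].
#' @param atlas An [atlas_bundle()].
#' @param affine 4x4 voxel-to-mm transform of the analysis grid.
#' @param component Component index these peaks belong to (stored in the
#'   output).
#' @param component_p Component-level p-value to attach (scalar).
#' @return Tibble: `component`, `cluster`, `region`, `network`,
#'   `peak_abs_z`, `p`, `x`, `y`, `z`, `n_voxels`.
#' @export
label_peaks <- function(peaks, atlas, affine, component = NA_integer_,
                        component_p = NA_real_) {
  stopifnot(inherits(atlas, "atlas_bundle"))
  if (nrow(peaks) == 0L) {
    return(tibble(component = integer(0), cluster = integer(0),
                  region = character(0), network = character(0),
                  peak_abs_z = numeric(0), p = numeric(0),
                  x = numeric(0), y = numeric(0), z = numeric(0),
                  n_voxels = integer(0)))
  }
  d <- dim(atlas$label_volume)
  if (any(peaks$i >= d[1] | peaks$j >= d[2] | peaks$k >= d[3])) {
    stopf("peak voxel outside the atlas grid (%s); grids must match.",
          paste(d, collapse = "x"), class = "picafuse_grid_error")
  }
  lab_ids <- atlas$label_volume[cbind(peaks$i + 1L, peaks$j + 1L, peaks$k + 1L)]
  region <- vapply(lab_ids, function(id) {
    if (id == 0) return("unassigned")
    atlas$label_table$region_name[match(id, atlas$label_table$label_id)]
  }, character(1))
  mm <- voxel_to_mm(as.matrix(peaks[, c("i", "j", "k")]), affine)
  out <- peaks |>
    mutate(component = component,
           region = region,
           network = dplyr::coalesce(
             atlas$network_map$network[match(region, atlas$network_map$region_name)],
             "unassigned"),
           p = component_p,
           x = mm[, 1], y = mm[, 2], z = mm[, 3]) |>
    select("component", "cluster", "region", "network",
           "peak_abs_z", "p", "x", "y", "z", "n_voxels")
  if (any(out$region == "unassigned")) {
    message(sprintf("%d peak(s) fell outside any labelled region.",
                    sum(out$region == "unassigned")))
  }
  out
}

#' A small synthetic atlas for testing and demonstration
#'
#' A handful of labelled ellipsoids on the analysis grid, each assigned to a
#' canonical network class (default-mode, visual, cognitive, subcortical).
#' This is a synthetic stand-in used by the examples and test-suite; real
#' deployments supply their own label volume and lookup tables.
#'
#' @param grid_dims Three grid dimensions.
#' @param n_regions Number of ellipsoid regions (2 to 8).
#' @return An [atlas_bundle()].
#' @export
synthetic_atlas <- function(grid_dims, n_regions = 6L) {
  stopifnot(n_regions >= 2L, n_regions <= 8L)
  vol <- array(0L, grid_dims)
  # region centres at fixed fractional positions of the grid
  fracs <- cbind(
    c(0.35, 0.35, 0.35), c(0.65, 0.65, 0.65), c(0.35, 0.65, 0.5),
    c(0.65, 0.35, 0.5), c(0.5, 0.5, 0.3), c(0.5, 0.5, 0.7),
    c(0.3, 0.5, 0.6), c(0.7, 0.5, 0.4)
  )
  radius <- pmax(grid_dims * 0.14, 2)
  for (r in seq_len(n_regions)) {
    centre <- fracs[, r] * grid_dims
    i <- slice.index(vol, 1L); j <- slice.index(vol, 2L); k <- slice.index(vol, 3L)
    inside <- ((i - centre[1]) / radius[1])^2 + ((j - centre[2]) / radius[2])^2 +
      ((k - centre[3]) / radius[3])^2 <= 1
    vol[inside] <- r
  }
  networks <- rep(c("DMN", "visual", "cognitive", "subcortical"), 2L)[seq_len(n_regions)]
  atlas_bundle(
    vol,
    tibble(label_id = seq_len(n_regions),
           region_name = sprintf("region_%02d", seq_len(n_regions))),
    tibble(region_name = sprintf("region_%02d", seq_len(n_regions)),
           network = networks)
  )
}

#' Peak table for every significant component of a fit
#'
#' Convenience wrapper: z-scores each significant component's source map,
#' thresholds it, finds clusters and labels their peaks against the atlas.
#'
#' @param fit A `pica_fit`.
#' @param tests Output of [loading_group_test()] for the matching modality.
#' @param atlas An [atlas_bundle()].
#' @param modality Modality index (1 or 2).
#' @param z_cutoff Cluster-forming |z| threshold.
#' @param connectivity Cluster connectivity.
#' @return Tibble of labelled peaks across significant components.
#' @export
atlas_report <- function(fit, tests, atlas, modality = 1L, z_cutoff = 2.5,
                         connectivity = 26L) {
  mod <- fit$modalities[[modality]]
  if (is.null(mod$mask)) {
    stopf("fit carries no mask for modality %d; fit on voxel_matrix inputs.",
          modality, class = "picafuse_domain_error")
  }
  sig <- tests$component[tests$significant]
  out <- map(sig, function(comp) {
    z <- zscore_map(mod$sources[comp, ])
    zvol <- unflatten(z, mod$mask)
    peaks <- find_peaks(zvol, threshold = z_cutoff, connectivity = connectivity)
    label_peaks(peaks, atlas, mod$affine, component = comp,
                component_p = tests$p[tests$component == comp])
  })
  bind_rows(out)
}
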