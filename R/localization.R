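#' Map physical cell centroids to voxel indices
#'
#' Voxel `i` (0-based) covers the half-open interval
#' `[i*s - s/2, i*s + s/2)` on each axis, so the containing voxel of a
#' coordinate `c` is `floor(c/s + 1/2)`. Returns 1-based R indices.
#'
#' @param cells Data frame with columns `x_um`, `y_um` and optionally
#'   `z_um`; a `cell_id` column is used in error messages.
#' @param dim_grid Grid dimensions `(ny, nx[, nz])`.
#' @param spacing Per-axis voxel size `(y, x[, z])` in micrometres.
#' @return Integer matrix with one row per cell, columns `(iy, ix[, iz])`.
#' @keywords internal
cells_to_voxels <- function(cells, dim_grid, spacing) {
  nd <- length(dim_grid)
  cols <- if (nd == 3L) c("y_um", "x_um", "z_um") else c("y_um", "x_um")
  missing_cols <- setdiff(cols, names(cells))
  if (length(missing_cols))
    stop("cell table lacks column(s): ", paste(missing_cols, collapse = ", "))
  idx <- matrix(NA_integer_, nrow(cells), nd)
  for (a in seq_len(nd)) {
    idx[, a] <- as.integer(floor(cells[[cols[a]]] / spacing[a] + 0.5)) + 1L
  }
  bad <- which(apply(idx, 1L, function(r)
    any(r < 1L) || any(r > dim_grid)))
  if (length(bad)) {
    ids <- if ("cell_id" %in% names(cells)) cells$cell_id[bad] else bad
    stop("cell centroid(s) outside the grid: ",
         paste(utils::head(ids, 5L), collapse = ", "))
  }
  idx
}

#' Count cells inside versus outside lymphatic vessels
#'
#' A cell is inside iff the voxel containing its centroid is mask
#' foreground. The inside count is normalized to the vessel volume computed
#' from the mask, yielding an intravascular density (cells per um^3 in 3D,
#' per um^2 in 2D); the in-versus-out ratio is reported when at least one
#' cell lies outside, otherwise flagged undefined (not infinity).
#'
#' @param cells Data frame of cell centroids (`x_um`, `y_um`[, `z_um`]).
#' @param scene A [vessel_scene()] (or a list with `mask` and `spacing`).
#' @return An `in_out_result`: list with `n_inside`, `n_outside`,
#'   `vessel_volume`, `inside_density`, `in_out_ratio` (NA when undefined)
#'   and logical `ratio_defined`.
#' @export
classify_in_out <- function(cells, scene) {
  mask <- scene$mask
  spacing <- scene$spacing
  if (!any(mask)) stop("vessel mask is empty")
  idx <- cells_to_voxels(cells, dim(mask), spacing)
  inside <- mask[idx]
  vol <- mask_volume(mask, spacing)
  n_in <- sum(inside)
  n_out <- sum(!inside)
  structure(
    list(n_inside = n_in, n_outside = n_out, vessel_volume = vol,
         inside_density = n_in / vol,
         in_out_ratio = if (n_out > 0) n_in / n_out else NA_real_,
         ratio_defined = n_out > 0,
         inside = inside, ndim = length(dim(mask))),
    class = "in_out_result"
  )
}

#' @export
print.in_out_result <- function(x, ...) {
  unit <- if (identical(x$ndim, 2L)) "um^2" else "um^3"
  cat("<in_out_result> in:", x$n_inside, " out:", x$n_outside,
      " vessel volume:", format(x$vessel_volume, digits = 6), unit,
      " density:", format(x$inside_density, digits = 4),
      paste0("cells/", unit), "\n")
  invisible(x)
}

#' Distance from each cell centroid to the nearest vessel
#'
#' Looks up the distance-map value at the voxel containing each centroid;
#' 0 for intravascular cells. Optionally reports a surface-style distance
#' (centroid distance minus a configured mean vessel radius, floored at 0),
#' mirroring analyses that subtract an average vessel radius measured from
#' a sample of vessels.
#'
#' @param cells Data frame of cell centroids.
#' @param dmap A `distance_map`.
#' @param mean_radius Optional mean vessel radius in micrometres; when
#'   given, a `surface_distance_um` column is added.
#' @return `cells` with a `distance_um` column appended.
#' @export
distance_to_vessel <- function(cells, dmap, mean_radius = NULL) {
  idx <- cells_to_voxels(cells, dim(dmap$values), dmap$spacing)
  cells$distance_um <- dmap$values[idx]
  if (!is.null(mean_radius)) {
    cells$surface_distance_um <- pmax(cells$distance_um - mean_radius, 0)
  }
  cells
}

#' Relative distribution of cells across distance zones
#'
#' Counts cells by the zone label of the voxel containing each centroid and
#' reports fractions of the total, reproducing the zone-segmented
#' accumulation readout of short crawl-in assays.
#'
#' @param cells Data frame of cell centroids.
#' @param zone_map A `zone_map` from [make_zone_map()].
#' @param spacing Per-axis voxel spacing of the grid the zone map lives on.
#' @return A `zone_distribution`: data.frame with columns `zone`
#'   (0 = on-vessel, `length(edges)` = beyond last edge), `lower_um`,
#'   `upper_um`, `count`, `fraction` (all-NA fractions when there are no
#'   cells, with attribute `defined = FALSE`).
#' @export
zone_distribution <- function(cells, zone_map, spacing) {
  stopifnot(inherits(zone_map, "zone_map"))
  edges <- zone_map$edges
  k <- length(edges)
  zones <- 0:k
  lower <- c(NA, edges)
  upper <- c(NA, edges[-1L], Inf)
  if (nrow(cells) > 0L) {
    idx <- cells_to_voxels(cells, dim(zone_map$labels), spacing)
    lab <- zone_map$labels[idx]
    cnt <- as.integer(table(factor(lab, levels = zones)))
    frac <- cnt / sum(cnt)
    defined <- TRUE
  } else {
    cnt <- integer(k + 1L)
    frac <- rep(NA_real_, k + 1L)
    defined <- FALSE
  }
  out <- data.frame(zone = zones, lower_um = lower, upper_um = upper,
                    count = cnt, fraction = frac)
  attr(out, "defined") <- defined
  class(out) <- c("zone_distribution", "data.frame")
  out
}

#' Chemokine intensity ratio between Golgi-high and Golgi-low regions
#'
#' Within the LYVE-1 (lymphatic endothelial) mask, pixels are split into
#' GOLPH4-high versus GOLPH4-low regions by a quantile threshold on the
#' Golgi-marker intensity (default: upper quartile within the mask). The
#' isotype-control MFI is subtracted from the mean chemokine intensity of
#' each region and the high/low ratio reported; the ratio is flagged
#' undefined when a region is empty or the low region's corrected MFI is 0.
#'
#' @param ccl21_image,golph4_image Numeric arrays sharing a shape.
#' @param lyve1_mask Logical array, same shape, non-empty.
#' @param isotype_mfi Scalar isotype-control mean fluorescence intensity
#'   (default 0).
#' @param golgi_quantile Quantile of GOLPH4 intensity within the mask that
#'   separates high from low (default 0.75).
#' @return List with `mfi_high`, `mfi_low`, `ratio` (NA when undefined),
#'   `ratio_defined`, `threshold` and region pixel counts.
#' @export
golgi_ratio <- function(ccl21_image, lyve1_mask, golph4_image,
                        isotype_mfi = 0, golgi_quantile = 0.75) {
  if (!identical(dim(ccl21_image) %||% length(ccl21_image),
                 dim(golph4_image) %||% length(golph4_image)) ||
      !identical(dim(ccl21_image) %||% length(ccl21_image),
                 dim(lyve1_mask) %||% length(lyve1_mask)))
    stop("images and mask must share one shape")
  if (!is.logical(lyve1_mask)) storage.mode(lyve1_mask) <- "logical"
  if (!any(lyve1_mask)) stop("LYVE-1 mask is empty")
  g <- golph4_image[lyve1_mask]
  c21 <- ccl21_image[lyve1_mask]
  thr <- quantile(g, golgi_quantile, names = FALSE)
  hi <- g > thr
  n_hi <- sum(hi); n_lo <- sum(!hi)
  mfi_high <- if (n_hi) max(mean(c21[hi]) - isotype_mfi, 0) else NA_real_
  mfi_low <- if (n_lo) max(mean(c21[!hi]) - isotype_mfi, 0) else NA_real_
  defined <- n_hi > 0 && n_lo > 0 && isTRUE(mfi_low > 0)
  list(mfi_high = mfi_high, mfi_low = mfi_low,
       ratio = if (defined) mfi_high / mfi_low else NA_real_,
       ratio_defined = defined, threshold = thr,
       n_high = n_hi, n_low = n_lo)
}
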