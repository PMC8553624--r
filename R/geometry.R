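#' Vessel scene: intensity stack, binary vessel mask and voxel spacing
#'
#' The unit of data every imaging stage consumes. Arrays are stored in R's
#' column-major layout with axis order `(y, x)` for 2D scenes and
#' `(y, x, z)` for 3D stacks; `spacing` gives the physical voxel size in
#' micrometres per axis, in the same order. Voxel centres sit at
#' `index0 * spacing` (0-based indices), so all physical coordinates are
#' voxel-centre coordinates.
#'
#' @param intensity Numeric array (2D or 3D), or a named list of such arrays
#'   for multichannel scenes (all channels share one shape).
#' @param mask Logical array with the shape of one intensity channel;
#'   `TRUE` marks vessel (lymphatic) voxels.
#' @param spacing Numeric vector of per-axis voxel size in micrometres,
#'   one entry per array dimension; all entries must be positive.
#' @param time_label Optional clock time in hours on a 24-h wheel (ZT/CT).
#' @param meta Optional free-text provenance string.
#' @return An object of class `vessel_scene`.
#' @export
vessel_scene <- function(intensity, mask, spacing, time_label = NULL,
                         meta = "") {
  channels <- if (is.list(intensity)) intensity else list(main = intensity)
  shape <- dim(channels[[1L]]) %||% length(channels[[1L]])
  for (ch in channels) {
    if (!identical(dim(ch) %||% length(ch), shape))
      stop("all intensity channels must share one shape")
  }
  if (!is.logical(mask)) {
    storage.mode(mask) <- "logical"
  }
  if (!identical(dim(mask) %||% length(mask), shape))
    stop("mask shape must equal the intensity channel shape")
  spacing <- as.numeric(spacing)
  if (length(spacing) != length(shape))
    stop("spacing must have one entry per array dimension")
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be strictly positive on every axis")
  if (!is.null(time_label)) {
    time_label <- as.numeric(time_label) %% 24
  }
  structure(
    list(intensity = channels, mask = mask, spacing = spacing,
         time_label = time_label, meta = meta),
    class = "vessel_scene"
  )
}

#' @export
print.vessel_scene <- function(x, ...) {
  cat("<vessel_scene> ", paste(dim(x$mask), collapse = "x"),
      " voxels @ (", paste(x$spacing, collapse = ", "), ") um; ",
      sum(x$mask), " vessel voxels; channels: ",
      paste(names(x$intensity), collapse = ", "), sep = "")
  if (!is.null(x$time_label)) cat("; t =", x$time_label, "h")
  cat("\n")
  invisible(x)
}

#' Rasterize closed polygon outlines into a binary mask
#'
#' Emulates manual outlining of lymphatic capillaries: each polygon, given in
#' micrometre coordinates, is filled on the voxel grid. A voxel belongs to
#' the mask iff its centre lies inside a polygon or on its boundary
#' (even-odd rule with an explicit on-edge test).
#'
#' @param outlines A list of polygons; each a two-column matrix/data.frame of
#'   `(x_um, y_um)` vertices (closed implicitly; >= 3 vertices).
#' @param grid_shape Integer vector `(ny, nx)` of the target grid.
#' @param spacing Per-axis voxel size `(y, x)` in micrometres.
#' @return Logical `(ny, nx)` matrix.
#' @export
rasterize_outlines <- function(outlines, grid_shape, spacing) {
  if (!is.list(outlines) || length(outlines) == 0L)
    stop("outlines must be a non-empty list of polygons")
  grid_shape <- as.integer(grid_shape)
  spacing <- as.numeric(spacing)
  stopifnot(length(grid_shape) == 2L, length(spacing) == 2L,
            all(spacing > 0))
  ny <- grid_shape[1L]; nx <- grid_shape[2L]
  x_max <- (nx - 1L) * spacing[2L]
  y_max <- (ny - 1L) * spacing[1L]
  mask <- matrix(FALSE, ny, nx)
  xs <- (seq_len(nx) - 1L) * spacing[2L]
  ys <- (seq_len(ny) - 1L) * spacing[1L]
  for (p in seq_along(outlines)) {
    poly <- as.matrix(outlines[[p]])
    if (nrow(poly) < 3L)
      stop("polygon ", p, " has fewer than 3 vertices")
    if (any(poly[, 1L] < 0) || any(poly[, 1L] > x_max) ||
        any(poly[, 2L] < 0) || any(poly[, 2L] > y_max))
      stop("polygon ", p, " extends outside the grid extent")
    # restrict to the polygon's bounding box on the voxel grid
    ix <- which(xs >= min(poly[, 1L]) - spacing[2L] &
                xs <= max(poly[, 1L]) + spacing[2L])
    iy <- which(ys >= min(poly[, 2L]) - spacing[1L] &
                ys <= max(poly[, 2L]) + spacing[1L])
    if (!length(ix) || !length(iy)) next
    pts <- cbind(x = rep(xs[ix], each = length(iy)),
                 y = rep(ys[iy], times = length(ix)))
    inside <- point_in_polygon(pts, poly)
    mask[cbind(rep(iy, times = length(ix)),
               rep(ix, each = length(iy)))] <-
      mask[cbind(rep(iy, times = length(ix)),
                 rep(ix, each = length(iy)))] | inside
  }
  mask
}

# Even-odd crossing test, boundary-inclusive. pts: n x 2 (x, y); poly: m x 2.
point_in_polygon <- function(pts, poly) {
  n <- nrow(pts)
  m <- nrow(poly)
  inside <- rep(FALSE, n)
  on_edge <- rep(FALSE, n)
  px <- pts[, 1L]; py <- pts[, 2L]
  eps <- 1e-9
  j <- m
  for (i in seq_len(m)) {
    xi <- poly[i, 1L]; yi <- poly[i, 2L]
    xj <- poly[j, 1L]; yj <- poly[j, 2L]
    # on-segment test
    dx <- xj - xi; dy <- yj - yi
    len2 <- dx * dx + dy * dy
    if (len2 > 0) {
      t <- pmin(1, pmax(0, ((px - xi) * dx + (py - yi) * dy) / len2))
      d2 <- (xi + t * dx - px)^2 + (yi + t * dy - py)^2
      on_edge <- on_edge | d2 <= eps^2
    } else {
      on_edge <- on_edge | ((px - xi)^2 + (py - yi)^2 <= eps^2)
    }
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Exact Euclidean distance transform of a binary mask, in micrometres
#'
#' For every voxel, the shortest Euclidean distance (using the per-axis
#' physical spacing) from its centre to the centre of the nearest mask
#' foreground voxel; exactly 0 on foreground. The transform is exact (not
#' chamfer/approximate): it is the separable lower-envelope algorithm on
#' squared distances, which decompose additively over axes even under
#' anisotropic spacing.
#'
#' @param mask Logical array (2D or 3D) with at least one `TRUE` voxel.
#' @param spacing Per-axis voxel size in micrometres (same length as
#'   `dim(mask)`).
#' @return An object of class `distance_map`: list with `values` (numeric
#'   array of distances in um, same shape as `mask`) and `spacing`.
#' @export
distance_transform <- function(mask, spacing) {
  if (!is.logical(mask)) storage.mode(mask) <- "logical"
  d <- dim(mask) %||% length(mask)
  spacing <- as.numeric(spacing)
  if (length(spacing) != length(d))
    stop("spacing must have one entry per mask dimension")
  if (any(spacing <= 0)) stop("spacing must be strictly positive")
  if (!any(mask)) stop("mask has no foreground voxels; distance undefined")
  dim3 <- c(d, rep(1L, 3L - length(d)))
  sp3 <- c(spacing, rep(1, 3L - length(spacing)))
  sq <- .edt_sq(as.logical(mask), as.integer(dim3), as.numeric(sp3))
  values <- array(sqrt(sq), dim = d)
  structure(list(values = values, spacing = spacing),
            class = "distance_map")
}

#' @export
print.distance_map <- function(x, ...) {
  cat("<distance_map> ", paste(dim(x$values), collapse = "x"),
      " voxels; range [", format(min(x$values), digits = 4), ", ",
      format(max(x$values), digits = 4), "] um\n", sep = "")
  invisible(x)
}

#' Segment a distance map into concentric distance zones
#'
#' Builds an integer zone-label map from a distance map: label 0 marks
#' on-vessel voxels (distance 0 on mask foreground), labels `1..K-1` the
#' half-open distance bands `[edges[i], edges[i+1])`, and the sentinel label
#' `length(edges)` all voxels at or beyond the last edge.
#'
#' @param dmap A `distance_map` from [distance_transform()].
#' @param edges Ascending distance-bin edges in micrometres, starting at 0.
#'   Default `c(0, 10, 20, 40, 80)`.
#' @return An object of class `zone_map`: list with `labels` (integer array)
#'   and `edges`.
#' @export
make_zone_map <- function(dmap, edges = c(0, 10, 20, 40, 80)) {
  stopifnot(inherits(dmap, "distance_map"))
  edges <- as.numeric(edges)
  if (length(edges) < 2L || any(diff(edges) <= 0))
    stop("edges must be strictly increasing")
  if (edges[1L] != 0) stop("first edge must be 0")
  v <- dmap$values
  lab <- findInterval(v, edges, rightmost.closed = FALSE)
  # voxels beyond the last edge already carry length(edges); on-vessel
  # voxels (exactly 0, necessarily foreground) are forced to label 0
  lab[v == 0] <- 0L
  structure(list(labels = array(as.integer(lab), dim = dim(v)),
                 edges = edges),
            class = "zone_map")
}

#' Physical volume (3D) or area (2D) of a binary mask
#'
#' Foreground voxel count times the voxel volume (product of per-axis
#' spacings). Used to normalize intravascular cell counts to vessel volume.
#'
#' @inheritParams distance_transform
#' @return Volume in um^3 (3D) or area in um^2 (2D); 0 for an empty mask.
#' @export
mask_volume <- function(mask, spacing) {
  if (!is.logical(mask)) storage.mode(mask) <- "logical"
  spacing <- as.numeric(spacing)
  d <- dim(mask) %||% length(mask)
  if (length(spacing) != length(d))
    stop("spacing must have one entry per mask dimension")
  if (any(spacing <= 0)) stop("spacing must be strictly positive")
  sum(mask) * prod(spacing)
}
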