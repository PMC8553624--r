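#' Read an intensity stack or mask with its voxel spacing
#'
#' Reads a grayscale TIFF and attaches spacing from an explicit argument or
#' a sidecar JSON (`{"spacing_um": [x, y, z]}`, conventionally at
#' `<path>.json`). Spacing is mandatory: core stages work in micrometres,
#' never in pixels. Sidecar spacing is given as `(x, y, z)` and mapped to
#' the internal `(y, x, z)` axis order; 2D files become single-plane 3D
#' grids unless `drop = TRUE`.
#'
#' @param path TIFF file.
#' @param spacing Per-axis `(y, x, z)` spacing in um, or `NULL` to read the
#'   sidecar.
#' @param sidecar Sidecar JSON path (default `<path>.json`).
#' @param drop Drop a singleton z axis (default `FALSE`).
#' @return List with `data` (numeric array) and `spacing`.
#' @export
read_stack <- function(path, spacing = NULL,
                       sidecar = paste0(path, ".json"), drop = FALSE) {
  arr <- read_tiff(path)
  if (is.null(spacing)) {
    if (!file.exists(sidecar))
      stop("no spacing given and no sidecar found at ", sidecar,
           "; supply spacing explicitly (um)")
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(sc$spacing_um))
      stop("sidecar ", sidecar, " lacks a 'spacing_um' field")
    s <- as.numeric(sc$spacing_um) # (x, y, z)
    spacing <- c(s[2L], s[1L], if (length(s) >= 3L) s[3L] else 1)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) == 2L) spacing <- c(spacing, 1)
  if (any(spacing <= 0)) stop("spacing must be strictly positive")
  if (drop && dim(arr)[3L] == 1L) {
    arr <- arr[, , 1L]
    spacing <- spacing[1:2]
  }
  list(data = arr, spacing = spacing)
}

#' Write a stack plus its spacing sidecar
#'
#' @param x Numeric array `(y, x[, z])`.
#' @param path Output TIFF path.
#' @param spacing Per-axis `(y, x[, z])` spacing in um (written to the
#'   sidecar as `(x, y, z)`).
#' @param bits Sample depth passed to [write_tiff()].
#' @return `path`, invisibly.
#' @export
write_stack <- function(x, path, spacing, bits = 32L) {
  write_tiff(x, path, bits = bits)
  s <- as.numeric(spacing)
  xyz <- if (length(s) == 2L) c(s[2L], s[1L], 1) else c(s[2L], s[1L], s[3L])
  jsonlite::write_json(list(spacing_um = xyz), paste0(path, ".json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Export a zone map as a label TIFF plus JSON edge list
#'
#' @param zone_map A `zone_map`.
#' @param path Output TIFF path (edges go to `<path>.zones.json`).
#' @return `path`, invisibly.
#' @export
write_zone_map <- function(zone_map, path) {
  stopifnot(inherits(zone_map, "zone_map"))
  write_tiff(zone_map$labels, path, bits = 16L)
  jsonlite::write_json(list(edges_um = zone_map$edges),
                       paste0(path, ".zones.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

# schema-checked CSV reading; numeric_cols are validated with row numbers
read_table_checked <- function(path, required, numeric_cols,
                               what = "table") {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(what, " file ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "))
  for (col in intersect(numeric_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "")
    if (length(bad))
      stop(what, " file ", path, ": non-numeric '", col, "' at row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "))
    df[[col]] <- v
  }
  df
}

#' Read a cell centroid table
#'
#' Requires columns `cell_id`, `x_um`, `y_um`; `z_um` and `label` are
#' optional, unknown columns are preserved.
#'
#' @param path CSV file.
#' @return Data frame of cells.
#' @export
read_cells <- function(path) {
  read_table_checked(path, c("cell_id", "x_um", "y_um"),
                     c("x_um", "y_um", "z_um"), "cells")
}

#' Read a track table
#'
#' Requires columns `track_id`, `frame`, `t_s`, `x_um`, `y_um`; `group` is
#' optional.
#'
#' @param path CSV file.
#' @return Data frame of track samples.
#' @export
read_tracks <- function(path) {
  read_table_checked(path, c("track_id", "frame", "t_s", "x_um", "y_um"),
                     c("frame", "t_s", "x_um", "y_um"), "tracks")
}

#' Read a rhythm series table
#'
#' Requires columns `time_h` and `value`; `replicate_id` and `group_id`
#' are optional.
#'
#' @param path CSV file.
#' @return Data frame of observations.
#' @export
read_series <- function(path) {
  read_table_checked(path, c("time_h", "value"), c("time_h", "value"),
                     "series")
}

#' Read a bioluminescence recording
#'
#' Requires columns `time_min` and `counts`.
#'
#' @param path CSV file.
#' @return Data frame with the recording.
#' @export
read_lumi <- function(path) {
  read_table_checked(path, c("time_min", "counts"), c("time_min", "counts"),
                     "lumi")
}

#' Read polygon outlines
#'
#' CSV with columns `polygon_id`, `vertex_index`, `x_um`, `y_um`; returns
#' the list-of-matrices form [rasterize_outlines()] consumes.
#'
#' @param path CSV file.
#' @return Named list of two-column vertex matrices.
#' @export
read_polygons <- function(path) {
  df <- read_table_checked(path,
                           c("polygon_id", "vertex_index", "x_um", "y_um"),
                           c("vertex_index", "x_um", "y_um"), "polygons")
  out <- lapply(split(df, df$polygon_id), function(p) {
    p <- p[order(p$vertex_index), , drop = FALSE]
    cbind(x_um = p$x_um, y_um = p$y_um)
  })
  out
}

#' Write a distance profile table
#'
#' Columns: `sample_id`, `time_label`, `bin_center_um`, `mean_intensity`,
#' `n_voxels`.
#'
#' @param profile A `distance_profile`.
#' @param path Output CSV.
#' @param sample_id,time_label Overrides for the profile attributes.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path, sample_id = NULL,
                          time_label = NULL) {
  df <- data.frame(
    sample_id = sample_id %||% attr(profile, "source") %||% NA_character_,
    time_label = time_label %||% attr(profile, "time_label") %||% NA_real_,
    bin_center_um = profile$bin_center_um,
    mean_intensity = profile$mean_intensity,
    n_voxels = profile$n_voxels)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a distance profile table written by [write_profile()]
#'
#' @param path CSV file.
#' @return A `distance_profile`.
#' @export
read_profile <- function(path) {
  df <- read_table_checked(path,
                           c("bin_center_um", "mean_intensity", "n_voxels"),
                           c("bin_center_um", "mean_intensity", "n_voxels"),
                           "profile")
  out <- df[, c("bin_center_um", "mean_intensity", "n_voxels")]
  attr(out, "source") <- if ("sample_id" %in% names(df))
    df$sample_id[1L] else NA_character_
  attr(out, "time_label") <- if ("time_label" %in% names(df))
    df$time_label[1L] else NULL
  class(out) <- c("distance_profile", "data.frame")
  out
}
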