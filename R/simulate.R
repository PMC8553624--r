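#' Specification of a synthetic vessel scene
#'
#' Describes the world a synthetic whole-mount scene is generated from: a
#' tubular lymphatic vessel built from capsule segments (all points within
#' `radius_um` of a polyline), a peri-lymphatic chemokine gradient decaying
#' exponentially with distance from the vessel, and a circadian modulation
#' of the gradient's peak intensity. The default scene is a 256 x 256 x 30
#' voxel stack at (0.5, 0.5, 1.0) um — the anisotropy of a confocal stack
#' with 1-um z steps — holding one gently curved capsule of radius 15 um.
#' The default modulation (mesor 150, amplitude 50, acrophase 7 h) makes
#' the peak intensity at the day peak (ZT7) exactly twice the night trough
#' (ZT19), the day:night contrast the assay is built around.
#'
#' @param shape Grid dimensions `(ny, nx)` or `(ny, nx, nz)`.
#' @param spacing Voxel size in um per axis, same length as `shape`.
#' @param segments Matrix of capsule polyline vertices in um, columns
#'   `(x, y[, z])`; consecutive rows are joined by capsule segments.
#'   `NULL` gives a default curved tube spanning the grid in x.
#' @param radius_um Vessel radius in um.
#' @param lambda_um Gradient decay length in um.
#' @param baseline Additive intensity baseline `b`.
#' @param sigma Gaussian noise s.d. (additive, clamped at 0).
#' @param mesor,amplitude,acrophase_h 24-h cosine parameters of the peak
#'   intensity `I0(t) = mesor + amplitude*cos(2*pi*(t - acrophase_h)/24)`;
#'   `amplitude <= mesor` keeps expected intensities non-negative.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(shape = c(256L, 256L, 30L),
                       spacing = c(0.5, 0.5, 1.0),
                       segments = NULL, radius_um = 15,
                       lambda_um = 20, baseline = 10, sigma = 15,
                       mesor = 150, amplitude = 50, acrophase_h = 7) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  stopifnot(length(shape) %in% 2:3, length(spacing) == length(shape),
            all(spacing > 0), radius_um > 0, lambda_um > 0, sigma >= 0,
            amplitude >= 0, amplitude <= mesor)
  nd <- length(shape)
  if (is.null(segments)) {
    # gently curved tube spanning the grid left to right
    ext <- (shape - 1L) * spacing # (y, x[, z]) extents in um
    xs <- seq(0, ext[2L], length.out = 4L)
    ys <- ext[1L] * c(0.40, 0.55, 0.45, 0.60)
    segments <- if (nd == 3L)
      cbind(x = xs, y = ys, z = rep(ext[3L] / 2, 4L))
    else cbind(x = xs, y = ys)
  }
  segments <- as.matrix(segments)
  if (ncol(segments) != nd)
    stop("segments need ", nd, " coordinate columns for a ", nd, "D scene")
  structure(list(shape = shape, spacing = spacing, segments = segments,
                 radius_um = radius_um, lambda_um = lambda_um,
                 baseline = baseline, sigma = sigma, mesor = mesor,
                 amplitude = amplitude, acrophase_h = acrophase_h),
            class = "scene_spec")
}

# minimum distance from every voxel centre to a capsule polyline (um)
capsule_distance <- function(shape, spacing, segments) {
  nd <- length(shape)
  # voxel-centre coordinate grids; array axis order (y, x[, z]) maps to
  # physical columns (x, y[, z]) of `segments`
  ax <- lapply(seq_len(nd), function(a) (seq_len(shape[a]) - 1) * spacing[a])
  coords <- switch(as.character(nd),
    "2" = cbind(x = rep(ax[[2L]], each = shape[1L]),
                y = rep(ax[[1L]], times = shape[2L])),
    "3" = cbind(
      x = rep(rep(ax[[2L]], each = shape[1L]), times = shape[3L]),
      y = rep(ax[[1L]], times = shape[2L] * shape[3L]),
      z = rep(ax[[3L]], each = shape[1L] * shape[2L])))
  dmin <- rep(Inf, nrow(coords))
  for (s in seq_len(nrow(segments) - 1L)) {
    a <- segments[s, ]; b <- segments[s + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) {
      d2 <- rowSums(sweep(coords, 2L, a)^2)
    } else {
      t <- pmin(1, pmax(0, (sweep(coords, 2L, a) %*% ab) / len2))
      proj <- matrix(a, nrow(coords), length(a), byrow = TRUE) +
        t %*% t(ab)
      d2 <- rowSums((coords - proj)^2)
    }
    dmin <- pmin(dmin, sqrt(d2))
  }
  array(dmin, dim = shape)
}

#' Generate a synthetic vessel scene with known ground truth
#'
#' Builds the vessel mask (voxels within `radius_um` of the capsule
#' polyline), computes its exact distance transform, and renders the
#' chemokine channel as `I0(t) * exp(-d / lambda) + baseline` plus
#' Gaussian noise clamped at 0, with
#' `I0(t) = mesor + amplitude * cos(2*pi*(t - acrophase_h)/24)`. The
#' returned ground truth (mask, distance map, noiseless intensity, `I0`)
#' is for test assertions only; no analysis stage may read it.
#'
#' @param spec A [scene_spec()].
#' @param time_label Clock time in hours (sets the circadian modulation);
#'   `NULL` freezes `I0` at its mesor.
#' @param seed Integer seed; fixed seed gives a bit-identical scene.
#' @return List with `scene` (a [vessel_scene()]) and `truth` (list:
#'   `mask`, `dmap`, `noiseless`, `I0`).
#' @export
gen_scene <- function(spec, time_label = NULL, seed = NULL) {
  stopifnot(inherits(spec, "scene_spec"))
  ext <- (spec$shape - 1L) * spec$spacing
  phys <- spec$segments
  lim_hi <- if (ncol(phys) == 2L) c(ext[2L], ext[1L])
  else c(ext[2L], ext[1L], ext[3L])
  if (any(phys < -1e-9) || any(sweep(phys, 2L, lim_hi) > 1e-9))
    stop("vessel polyline extends outside the grid")
  dcap <- capsule_distance(spec$shape, spec$spacing, spec$segments)
  mask <- dcap <= spec$radius_um
  if (!any(mask)) stop("vessel mask is empty; enlarge radius or grid")
  dmap <- distance_transform(mask, spec$spacing)
  i0 <- if (is.null(time_label)) spec$mesor else
    spec$mesor + spec$amplitude *
      cos(2 * pi * (time_label - spec$acrophase_h) / 24)
  noiseless <- i0 * exp(-dmap$values / spec$lambda_um) + spec$baseline
  intensity <- if (spec$sigma > 0) {
    with_seed(seed, pmax(noiseless +
      array(rnorm(length(noiseless), 0, spec$sigma), dim = spec$shape), 0))
  } else noiseless
  scene <- vessel_scene(list(ccl21 = intensity), mask, spec$spacing,
                        time_label = time_label, meta = "synthetic")
  list(scene = scene,
       truth = list(mask = mask, dmap = dmap, noiseless = noiseless,
                    I0 = i0))
}

#' Place synthetic cells with distance-dependent density
#'
#' Places `round(inside_fraction * n_cells)` cells uniformly over vessel
#' voxels and the rest over interstitial voxels with sampling weight
#' `density_fun(d)` (or per-zone weights `zone_density` over
#' `zone_edges`). Cells sit at voxel centres plus a sub-voxel jitter
#' (at most `jitter` of a voxel, default 0.3) so each cell's containing
#' voxel — hence its true compartment and zone — is known exactly.
#'
#' @param scene A [vessel_scene()].
#' @param n_cells Number of cells.
#' @param inside_fraction Fraction placed inside the vessel.
#' @param density_fun Function of distance (um) giving the relative
#'   placement density outside the vessel; default uniform.
#' @param zone_density Optional per-zone relative densities (overrides
#'   `density_fun`), one value per zone band of `zone_edges` plus one for
#'   beyond the last edge.
#' @param zone_edges Zone edges used with `zone_density`
#'   (default `c(0, 10, 20, 40, 80)`).
#' @param jitter Sub-voxel jitter as a fraction of voxel size (< 0.5).
#' @param dmap Optional precomputed `distance_map` for the scene mask.
#' @param seed Integer seed.
#' @return List with `cells` (data.frame `cell_id`, `x_um`, `y_um`
#'   [, `z_um`]) and `truth` (data.frame with `inside` and `zone`).
#' @export
gen_cells <- function(scene, n_cells, inside_fraction = 0.3,
                      density_fun = NULL, zone_density = NULL,
                      zone_edges = c(0, 10, 20, 40, 80), jitter = 0.3,
                      dmap = NULL, seed = NULL) {
  stopifnot(inherits(scene, "vessel_scene"), n_cells >= 0,
            inside_fraction >= 0, inside_fraction <= 1, jitter < 0.5)
  mask <- scene$mask
  spacing <- scene$spacing
  nd <- length(dim(mask))
  dmap <- dmap %||% distance_transform(mask, spacing)
  zmap <- make_zone_map(dmap, zone_edges)
  with_seed(seed, {
    n_in <- round(inside_fraction * n_cells)
    n_out <- n_cells - n_in
    fg <- which(mask)
    bg <- which(!mask)
    if (n_in > 0 && !length(fg)) stop("no vessel voxels to place cells in")
    w <- if (!is.null(zone_density)) {
      zone_density[zmap$labels[bg]]
    } else if (!is.null(density_fun)) {
      density_fun(dmap$values[bg])
    } else rep(1, length(bg))
    if (any(w < 0) || !any(w > 0))
      stop("placement density must be non-negative and somewhere positive")
    vox <- c(if (n_in) sample(fg, n_in, replace = TRUE),
             if (n_out) sample(bg, n_out, replace = TRUE, prob = w))
    sub <- arrayInd(vox, dim(mask)) # (iy, ix[, iz]) 1-based
    jit <- matrix(runif(length(vox) * nd, -jitter, jitter),
                  ncol = nd)
    pos <- sweep((sub - 1L) + jit, 2L, spacing, "*")
    cells <- data.frame(cell_id = seq_along(vox),
                        x_um = pos[, 2L], y_um = pos[, 1L])
    if (nd == 3L) cells$z_um <- pos[, 3L]
    truth <- data.frame(cell_id = cells$cell_id,
                        inside = mask[vox],
                        zone = zmap$labels[vox],
                        distance_um = dmap$values[vox])
    list(cells = cells, truth = truth)
  })
}

#' Generate replicate measurements following a 24-h cosine
#'
#' Values are `mesor + amplitude*cos(2*pi*(t - acrophase_h)/24)` plus
#' Gaussian noise, at the four standard collection times ZT1/7/13/19 by
#' default, emulating a rhythmic immunofluorescence readout.
#'
#' @param mesor,amplitude,acrophase_h Cosine parameters.
#' @param sigma Gaussian noise s.d.
#' @param n_per_time Replicates per time point.
#' @param times Collection times in hours.
#' @param seed Integer seed.
#' @return Data frame with `time_h`, `value`, `replicate_id`.
#' @export
gen_rhythm_series <- function(mesor, amplitude, acrophase_h, sigma = 0,
                              n_per_time = 5L,
                              times = c(1, 7, 13, 19), seed = NULL) {
  stopifnot(sigma >= 0, n_per_time >= 1L)
  with_seed(seed, {
    t <- rep(times, each = n_per_time)
    mu <- mesor + amplitude * cos(2 * pi * (t - acrophase_h) / 24)
    data.frame(time_h = t,
               value = mu + if (sigma > 0) rnorm(length(t), 0, sigma) else 0,
               replicate_id = rep(seq_len(n_per_time), times = length(times)))
  })
}

#' Generate persistent, optionally biased random-walk migration tracks
#'
#' Correlated random walk at the live-imaging cadence (one frame every
#' 100 s): each new heading is the normalized mixture of the previous
#' heading (weight `persistence`) with a fresh random direction, then mixed
#' with the bias direction (weight `bias`). `bias = 1` yields perfectly
#' straight, co-oriented steps (directionality 1); `bias = 0` a pure
#' persistent random walk. Step lengths are log-normal with median
#' `step_um`.
#'
#' @param n_tracks Number of tracks.
#' @param n_steps Steps per track (default 30, i.e. 50 min at 100 s).
#' @param step_um Median step length in um (default 5).
#' @param step_sdlog Log-normal sdlog of step lengths (default 0.3;
#'   0 gives fixed steps).
#' @param persistence Heading persistence in `[0, 1)`.
#' @param bias Bias weight toward `bias_direction`, in `[0, 1]`.
#' @param bias_direction Unit-normalized target direction (default +x).
#' @param frame_interval_s Sampling interval in seconds (default 100).
#' @param origin_spread_um Tracks start uniformly in a square of this side.
#' @param group Optional group label attached to all tracks.
#' @param seed Integer seed.
#' @return Track table (`track_id`, `frame`, `t_s`, `x_um`, `y_um`,
#'   `group`).
#' @export
gen_tracks <- function(n_tracks = 50L, n_steps = 30L, step_um = 5,
                       step_sdlog = 0.3, persistence = 0.5, bias = 0,
                       bias_direction = c(1, 0), frame_interval_s = 100,
                       origin_spread_um = 200, group = NA_character_,
                       seed = NULL) {
  stopifnot(bias >= 0, bias <= 1, persistence >= 0, persistence < 1,
            frame_interval_s > 0, n_steps >= 1L)
  bdir <- bias_direction / sqrt(sum(bias_direction^2))
  with_seed(seed, {
    out <- vector("list", n_tracks)
    for (k in seq_len(n_tracks)) {
      pos <- matrix(0, n_steps + 1L, 2L)
      pos[1L, ] <- runif(2L, 0, origin_spread_um)
      ang0 <- runif(1L, 0, 2 * pi)
      v <- c(cos(ang0), sin(ang0))
      steps <- if (step_sdlog > 0)
        stats::rlnorm(n_steps, log(step_um), step_sdlog)
      else rep(step_um, n_steps)
      for (s in seq_len(n_steps)) {
        ang <- runif(1L, 0, 2 * pi)
        r <- c(cos(ang), sin(ang))
        v1 <- persistence * v + (1 - persistence) * r
        if (sum(v1^2) < 1e-12) v1 <- r
        v1 <- v1 / sqrt(sum(v1^2))
        h <- (1 - bias) * v1 + bias * bdir
        if (sum(h^2) < 1e-12) h <- bdir
        h <- h / sqrt(sum(h^2))
        pos[s + 1L, ] <- pos[s, ] + steps[s] * h
        v <- h
      }
      out[[k]] <- data.frame(
        track_id = k, frame = seq_len(n_steps + 1L),
        t_s = (seq_len(n_steps + 1L) - 1L) * frame_interval_s,
        x_um = pos[, 1L], y_um = pos[, 2L], group = group)
    }
    do.call(rbind, out)
  })
}

#' Generate a damped rhythmic bioluminescence recording
#'
#' Photon counts per minute following
#' `baseline + slope*t + amplitude*exp(-damping*t)*cos(2*pi*t/period)`
#' plus Gaussian noise, with `t` in hours — the signature of a synchronized
#' clock-reporter culture: a circadian oscillation damping out on top of a
#' slow luminescence trend.
#'
#' @param duration_h Recording length in hours (> 2 periods).
#' @param baseline Mean count level.
#' @param amplitude Initial oscillation amplitude.
#' @param damping Exponential damping rate per hour.
#' @param slope Linear trend in counts per hour.
#' @param sigma Gaussian noise s.d.
#' @param period Oscillation period in hours (default 24).
#' @param seed Integer seed.
#' @return Data frame with `time_min` and `counts`.
#' @export
gen_lumi <- function(duration_h = 96, baseline = 100, amplitude = 50,
                     damping = 0.01, slope = -0.2, sigma = 1,
                     period = 24, seed = NULL) {
  stopifnot(duration_h > 2 * period, sigma >= 0)
  t_min <- seq(0, duration_h * 60)
  th <- t_min / 60
  mu <- baseline + slope * th +
    amplitude * exp(-damping * th) * cos(2 * pi * th / period)
  with_seed(seed, {
    data.frame(time_min = t_min,
               counts = mu + if (sigma > 0) rnorm(length(th), 0, sigma)
               else 0)
  })
}
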