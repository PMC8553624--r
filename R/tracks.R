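#' Trim a recording to a frame window
#'
#' Keeps only samples whose frame index lies in the inclusive, 1-based
#' window `[first_frame, last_frame]` (e.g. frames 31 to 300 after
#' discarding an unstable initial period). Tracks left with fewer than two
#' samples are dropped; the dropped count is attached as an attribute and
#' reported via a message.
#'
#' @param tracks Data frame with columns `track_id`, `frame`, `t_s`,
#'   `x_um`, `y_um` (optional `group`).
#' @param first_frame,last_frame Inclusive 1-based window bounds.
#' @return Trimmed track table with attribute `n_dropped_tracks`.
#' @export
trim_frames <- function(tracks, first_frame, last_frame) {
  req <- c("track_id", "frame")
  miss <- setdiff(req, names(tracks))
  if (length(miss)) stop("track table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (first_frame < 1 || last_frame < first_frame)
    stop("invalid frame window [", first_frame, ", ", last_frame, "]")
  out <- tracks[tracks$frame >= first_frame & tracks$frame <= last_frame, ,
                drop = FALSE]
  n_samples <- table(out$track_id)
  short <- names(n_samples)[n_samples < 2L]
  lost <- union(short, setdiff(unique(tracks$track_id), out$track_id))
  if (length(lost)) {
    message(length(lost), " track(s) dropped: <2 samples in window")
    out <- out[!(out$track_id %in% short), , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "n_dropped_tracks") <- length(lost)
  out
}

#' Chemotaxis metrics for one track
#'
#' From ordered `(t, x, y)` samples: accumulated distance is the summed
#' step length; Euclidean distance the displacement between first and last
#' point; directionality (directness) their ratio, in `[0, 1]`, defined as 0
#' for a closed path; velocity the mean path speed, accumulated distance
#' over elapsed time. Mean instantaneous speed is also reported.
#'
#' @param t_s Timestamps in seconds (strictly increasing).
#' @param x_um,y_um Coordinates in micrometres.
#' @return List with `accumulated_um`, `euclidean_um`, `directionality`,
#'   `velocity_um_s`, `mean_step_speed_um_s`, `n_samples`.
#' @export
compute_metrics <- function(t_s, x_um, y_um) {
  n <- length(t_s)
  stopifnot(length(x_um) == n, length(y_um) == n)
  if (n < 2L) stop("a track needs >= 2 samples")
  o <- order(t_s)
  t_s <- t_s[o]; x_um <- x_um[o]; y_um <- y_um[o]
  if (any(diff(t_s) <= 0)) stop("duplicate timestamps in track")
  steps <- sqrt(diff(x_um)^2 + diff(y_um)^2)
  acc <- sum(steps)
  euc <- sqrt((x_um[n] - x_um[1L])^2 + (y_um[n] - y_um[1L])^2)
  elapsed <- t_s[n] - t_s[1L]
  list(
    accumulated_um = acc,
    euclidean_um = euc,
    directionality = if (acc > 0) euc / acc else 0,
    velocity_um_s = acc / elapsed,
    mean_step_speed_um_s = mean(steps / diff(t_s)),
    n_samples = n
  )
}

#' Chemotaxis metrics for a table of tracks
#'
#' Applies [compute_metrics()] per track. Tracks with frame gaps larger
#' than `max_gap` frames (missed detections bridged by straight segments)
#' are dropped and counted.
#'
#' @param tracks Data frame with columns `track_id`, `t_s`, `x_um`, `y_um`
#'   and optionally `frame` and `group`.
#' @param max_gap Largest tolerated frame gap (default 2); ignored when
#'   there is no `frame` column.
#' @return Data frame, one row per track, with the metric columns and
#'   attribute `n_dropped_tracks`.
#' @export
track_metrics <- function(tracks, max_gap = 2L) {
  req <- c("track_id", "t_s", "x_um", "y_um")
  miss <- setdiff(req, names(tracks))
  if (length(miss)) stop("track table lacks column(s): ",
                         paste(miss, collapse = ", "))
  ids <- unique(tracks$track_id)
  rows <- list()
  dropped <- 0L
  for (id in ids) {
    tr <- tracks[tracks$track_id == id, , drop = FALSE]
    tr <- tr[order(tr$t_s), , drop = FALSE]
    if (!is.null(tr$frame) && nrow(tr) > 1L &&
        any(diff(tr$frame) > max_gap + 1L)) {
      dropped <- dropped + 1L
      next
    }
    if (nrow(tr) < 2L) { dropped <- dropped + 1L; next }
    m <- compute_metrics(tr$t_s, tr$x_um, tr$y_um)
    rows[[length(rows) + 1L]] <- data.frame(
      track_id = id,
      group = if (!is.null(tr$group)) tr$group[1L] else NA,
      accumulated_um = m$accumulated_um, euclidean_um = m$euclidean_um,
      directionality = m$directionality, velocity_um_s = m$velocity_um_s,
      mean_step_speed_um_s = m$mean_step_speed_um_s,
      n_samples = m$n_samples
    )
  }
  if (dropped) message(dropped, " track(s) dropped (gaps or <2 samples)")
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(track_id = character(), group = character(),
               accumulated_um = numeric(), euclidean_um = numeric(),
               directionality = numeric(), velocity_um_s = numeric(),
               mean_step_speed_um_s = numeric(), n_samples = integer())
  rownames(out) <- NULL
  attr(out, "n_dropped_tracks") <- dropped
  out
}

#' Translate tracks to a common origin
#'
#' Shifts every track so its first sample lies at `(0, 0)`, the convention
#' for overlay ("rose") plots of migration tracks. Step vectors are
#' unchanged.
#'
#' @param tracks Track table (`track_id`, `t_s`, `x_um`, `y_um`).
#' @return The table with `x_um`, `y_um` replaced by origin-normalized
#'   coordinates.
#' @export
origin_normalize <- function(tracks) {
  req <- c("track_id", "t_s", "x_um", "y_um")
  miss <- setdiff(req, names(tracks))
  if (length(miss)) stop("track table lacks column(s): ",
                         paste(miss, collapse = ", "))
  out <- tracks[order(tracks$track_id, tracks$t_s), , drop = FALSE]
  for (id in unique(out$track_id)) {
    i <- which(out$track_id == id)
    out$x_um[i] <- out$x_um[i] - out$x_um[i[1L]]
    out$y_um[i] <- out$y_um[i] - out$y_um[i[1L]]
  }
  rownames(out) <- NULL
  out
}
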