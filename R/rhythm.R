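#' Fixed-period cosinor fit with zero-amplitude test
#'
#' Least-squares fit of `y = M + beta_c*cos(wt) + beta_s*sin(wt)` with
#' `w = 2*pi/period`, the standard single-component cosinor. Amplitude is
#' `A = sqrt(beta_c^2 + beta_s^2)` and the acrophase (clock time of the
#' fitted peak) is `phi = atan2(beta_s, beta_c)/w mod period`, so the fitted
#' curve is `M + A*cos(2*pi*(t - phi)/period)`. Rhythmicity is assessed by
#' the zero-amplitude F-test of `(beta_c, beta_s)` jointly zero against the
#' intercept-only model. The period is fixed at 24 h by default: designs
#' sampling four time points per cycle cannot identify a free period.
#'
#' @param time_h Clock times in hours (reduced mod `period`).
#' @param value Measurements, same length.
#' @param period Fixed period in hours (default 24).
#' @return A `cosinor_fit`: list with `mesor`, `amplitude`, `acrophase_h`,
#'   `p_zero_amplitude`, `residual_variance`, `n`, `period` and the raw
#'   cosine/sine coefficients.
#' @export
cosinor_fit <- function(time_h, value, period = 24) {
  stopifnot(length(time_h) == length(value), period > 0)
  ok <- is.finite(time_h) & is.finite(value)
  t <- as.numeric(time_h[ok]) %% period
  y <- as.numeric(value[ok])
  if (length(unique(t)) < 3L)
    stop("cosinor requires >= 3 distinct time points")
  if (length(y) < 4L)
    stop("cosinor requires >= 4 observations")
  w <- 2 * pi / period
  X <- cbind(ct = cos(w * t), st = sin(w * t))
  if (qr(cbind(1, X))$rank < 3L) stop("collinear cosinor design")
  fit <- lm(y ~ ct + st, data = data.frame(y = y, X))
  cf <- coef(fit)
  bc <- cf[["ct"]]; bs <- cf[["st"]]
  A <- sqrt(bc^2 + bs^2)
  phi <- (atan2(bs, bc) / w) %% period
  n <- length(y)
  rss1 <- sum(residuals(fit)^2)
  rss0 <- sum((y - mean(y))^2)
  df2 <- n - 3L
  if (df2 > 0 && rss1 > 0) {
    F <- ((rss0 - rss1) / 2) / (rss1 / df2)
    p <- pf(F, 2, df2, lower.tail = FALSE)
  } else {
    # saturated or perfect fit: amplitude is either exactly 0 or exact
    F <- if (rss0 > rss1) Inf else 0
    p <- if (rss0 > rss1) 0 else 1
  }
  structure(
    list(mesor = cf[[1L]], amplitude = A, acrophase_h = phi,
         p_zero_amplitude = p, F_statistic = F,
         residual_variance = if (df2 > 0) rss1 / df2 else NA_real_,
         n = n, period = period, beta_cos = bc, beta_sin = bs),
    class = "cosinor_fit"
  )
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf(
    "<cosinor_fit> mesor %.4g, amplitude %.4g, acrophase %.2f h (period %g h)\n",
    x$mesor, x$amplitude, x$acrophase_h, x$period))
  cat(sprintf("  zero-amplitude test: F = %.3g, p = %.3g, n = %d\n",
              x$F_statistic, x$p_zero_amplitude, x$n))
  invisible(x)
}

#' Evaluate a fitted cosinor curve
#'
#' @param object A `cosinor_fit`.
#' @param newdata Optional data frame with a `time_h` column (or a numeric
#'   vector of times).
#' @param ... Unused.
#' @return Fitted values `M + A*cos(2*pi*(t - phi)/period)`.
#' @export
predict.cosinor_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) seq(0, object$period, by = 0.5)
  else if (is.data.frame(newdata)) newdata$time_h else as.numeric(newdata)
  object$mesor + object$amplitude *
    cos(2 * pi * (t - object$acrophase_h) / object$period)
}

#' Immunofluorescence screen normalization for one molecule/tissue row
#'
#' Implements the screen convention: the mean isotype-control MFI is
#' subtracted from each time point's MFI (clamped at 0), values are divided
#' by the second-highest corrected value across time points (so that value
#' maps to 1.0; ties share the top value and normalize to 1.0), and the
#' molecule is flagged as expressed unless its maximum raw MFI falls below
#' `expression_threshold` (default 1.5%) of the screen-wide maximum MFI.
#'
#' @param raw_mfi Named numeric vector of per-ZT raw MFI (>= 2 time points).
#' @param isotype_mfi Isotype MFI values; their mean is subtracted.
#' @param screen_max Screen-wide maximum MFI used for the expression flag;
#'   defaults to `max(raw_mfi)` (single-row screens).
#' @param expression_threshold Fraction of `screen_max` below which the
#'   molecule is called no/low expression (default 0.015).
#' @return List with `normalized` (named vector), `corrected`,
#'   `second_highest`, `expressed`, `normalizable`.
#' @export
screen_normalize <- function(raw_mfi, isotype_mfi = 0, screen_max = NULL,
                             expression_threshold = 0.015) {
  raw <- as.numeric(raw_mfi)
  if (length(raw) < 2L) stop("screen normalization requires >= 2 ZTs")
  screen_max <- screen_max %||% max(raw)
  expressed <- max(raw) >= expression_threshold * screen_max
  corrected <- pmax(raw - mean(as.numeric(isotype_mfi)), 0)
  second <- sort(corrected, decreasing = TRUE)[2L]
  normalizable <- second > 0
  normalized <- if (normalizable) corrected / second
  else rep(NA_real_, length(corrected))
  names(normalized) <- names(raw_mfi)
  list(normalized = normalized, corrected = corrected,
       second_highest = second, expressed = expressed,
       normalizable = normalizable)
}

#' Pairwise fold-change matrix between time points
#'
#' Entry `(i, j)` is `value_i / value_j`; with positive inputs the matrix
#' satisfies the reciprocity `M[i,j] * M[j,i] = 1`. Zero denominators give
#' `NA` entries (flagged undefined rather than infinite).
#'
#' @param values Named numeric vector of normalized per-ZT values.
#' @return K x K numeric matrix with the input names on both dimensions.
#' @export
fold_change_matrix <- function(values) {
  v <- as.numeric(values)
  m <- outer(v, v, "/")
  m[!is.finite(m)] <- NA_real_
  m[, v == 0] <- NA_real_
  dimnames(m) <- list(names(values), names(values))
  m
}

#' Collapse many rhythmic profiles into one integrated profile
#'
#' Each profile (one molecule/gene/organ) is rescaled and the per-time-point
#' mean and s.e.m. across profiles computed, collapsing a family of rhythms
#' into one graph. The default rescaling is min-max to `[0, 1]`; z-score and
#' peak (divide-by-max) strategies are available since the collapse
#' normalization is a convention, not a measurement. Flat profiles
#' (max == min) cannot be min-max rescaled and are excluded with a warning.
#'
#' @param profiles List of numeric vectors, all on one shared time grid
#'   (names or a `times` argument give the grid).
#' @param times Time points in hours (defaults to names of the first
#'   profile, else its index).
#' @param method One of `"minmax"`, `"zscore"`, `"peak"`.
#' @return Data frame with `time_h`, `mean`, `sem`, `n_profiles`.
#' @export
integrate_profiles <- function(profiles, times = NULL,
                               method = c("minmax", "zscore", "peak")) {
  method <- match.arg(method)
  if (!length(profiles)) stop("no profiles to integrate")
  len <- unique(vapply(profiles, length, 1L))
  if (length(len) != 1L) stop("profiles must share one time grid")
  times <- times %||% {
    nm <- names(profiles[[1L]])
    if (!is.null(nm)) as.numeric(nm) else seq_len(len) - 1
  }
  rescale <- switch(method,
    minmax = function(x) {
      r <- range(x)
      if (diff(r) == 0) return(NULL)
      (x - r[1L]) / diff(r)
    },
    zscore = function(x) {
      s <- sd(x)
      if (s == 0) return(NULL)
      (x - mean(x)) / s
    },
    peak = function(x) {
      m <- max(x)
      if (m == 0) return(NULL)
      x / m
    })
  scaled <- lapply(profiles, rescale)
  drop <- vapply(scaled, is.null, TRUE)
  if (any(drop)) {
    warning(sum(drop), " flat profile(s) excluded from integration")
    scaled <- scaled[!drop]
  }
  if (!length(scaled)) stop("all profiles flat; nothing to integrate")
  m <- do.call(rbind, scaled)
  data.frame(
    time_h = times,
    mean = colMeans(m),
    sem = apply(m, 2L, sd) / sqrt(nrow(m)),
    n_profiles = nrow(m)
  )
}

#' Detrend a bioluminescence recording with a centered 24-h moving average
#'
#' Relative bioluminescence is the photon-count series minus its centered
#' moving average over one full period (subtraction is exact for additive
#' trends; division is available for multiplicative ones). Samples whose
#' full window does not fit — the first and last half-window, i.e. 12 h for
#' a 24-h window — are dropped, so the output is shorter than the input by
#' `window - 1` samples.
#'
#' @param time_min Regularly spaced timestamps in minutes.
#' @param counts Photon counts per minute, same length.
#' @param window_h Moving-average window in hours (default 24).
#' @param method `"subtract"` (default) or `"divide"`.
#' @return Data frame with `time_min`, `counts`, `trend`, `relative`.
#' @export
detrend_lumi <- function(time_min, counts, window_h = 24,
                         method = c("subtract", "divide")) {
  method <- match.arg(method)
  stopifnot(length(time_min) == length(counts), length(counts) > 2L)
  dt <- diff(time_min)
  if (any(abs(dt - dt[1L]) > 1e-6 * max(abs(dt[1L]), 1)))
    stop("sampling must be regular")
  dt <- dt[1L]
  if (dt <= 0) stop("timestamps must be strictly increasing")
  dur_h <- (time_min[length(time_min)] - time_min[1L]) / 60
  if (dur_h <= window_h)
    stop("series duration must exceed the detrending window (",
         window_h, " h)")
  nw <- floor(window_h * 60 / dt)
  if (nw %% 2L == 0L) nw <- nw + 1L # symmetric window
  trend <- as.numeric(stats::filter(counts, rep(1 / nw, nw), sides = 2))
  keep <- !is.na(trend)
  rel <- if (method == "subtract") counts[keep] - trend[keep]
  else counts[keep] / trend[keep]
  data.frame(time_min = time_min[keep], counts = counts[keep],
             trend = trend[keep], relative = rel)
}

#' One-way ANOVA across time points with Tukey post test
#'
#' @param time_h Group labels (clock times in hours).
#' @param value Measurements.
#' @return List with `F_statistic`, `p`, `df`, and `tukey` (the pairwise
#'   comparison table).
#' @export
timepoint_anova <- function(time_h, value) {
  g <- factor(time_h)
  if (nlevels(g) < 2L) stop("ANOVA requires >= 2 time points")
  if (any(table(g) < 2L)) stop("every time point needs >= 2 replicates")
  fit <- aov(value ~ g, data = data.frame(value = value, g = g))
  s <- summary(fit)[[1L]]
  list(F_statistic = s[["F value"]][1L], p = s[["Pr(>F)"]][1L],
       df = s[["Df"]], tukey = TukeyHSD(fit)$g)
}

#' Tiered significance annotation
#'
#' Maps a p value to the star annotation tiers 0.05/0.01/0.001/0.0001.
#'
#' @param p Numeric vector of p values.
#' @param symbol Symbol repeated per tier (default `"*"`).
#' @return Character vector ("ns" when not significant).
#' @export
significance_tier <- function(p, symbol = "*") {
  cuts <- c(1e-4, 1e-3, 1e-2, 5e-2)
  vapply(p, function(pi) {
    if (!is.finite(pi) || pi >= cuts[4L]) return("ns")
    strrep(symbol, 4L - findInterval(pi, cuts))
  }, "")
}
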