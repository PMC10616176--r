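# Elongation-time estimation from low-to-high fluorescence transitions.
#
# The time the MS2 signal needs to go from a (nearly) empty to a (nearly)
# full reporter is the elongation time in sampling steps. Events are
# collected with an 85th-percentile "high" threshold and a low threshold at
# 0.15 * f_high, aligned at the last sub-threshold frame, averaged, and the
# averaged event is segmented into plateau / ramp / plateau by exhaustive
# three-segment piecewise-linear least squares. The reported step count is
# the ramp line's crossing separation between the two plateau levels,
# which is exact on a noiseless w-step ramp and robust to the +/- 1-frame
# breakpoint ties of the raw change-point indices.

# exhaustive 3-segment piecewise-linear least squares; returns breakpoints
# (first index of segment 2 and of segment 3) and the per-segment fits
piecewise3_linear <- function(y) {
  n <- length(y)
  if (n < 6) abort_param("averaged event too short for segmentation")
  x <- seq_len(n)
  segfit <- function(i, j) {
    xs <- x[i:j]; ys <- y[i:j]
    mx <- mean(xs); my <- mean(ys)
    vx <- sum((xs - mx)^2)
    slope <- if (vx == 0) 0 else sum((xs - mx) * (ys - my)) / vx
    sse <- sum((ys - (my + slope * (xs - mx)))^2)
    list(sse = sse, slope = slope, intercept = my - slope * mx, mean = my)
  }
  best <- NULL
  for (a in 2:(n - 4)) {
    f1 <- segfit(1, a)
    for (b in (a + 2):(n - 2)) {
      f2 <- segfit(a + 1, b)
      f3 <- segfit(b + 1, n)
      sse <- f1$sse + f2$sse + f3$sse
      if (is.null(best) || sse < best$sse - 1e-12) {
        best <- list(sse = sse, a = a, b = b, seg1 = f1, seg2 = f2, seg3 = f3)
      }
    }
  }
  best
}

#' Estimate the elongation time from an MS2 trace cohort
#'
#' @param traces List of numeric traces, or a long table with `cell_id` and
#'   `ms2_au`.
#' @param dt Sampling step in seconds.
#' @param f_high_q Quantile of the pooled intensities defining the "high"
#'   threshold (default 0.85).
#' @param f_low_frac Low threshold as a fraction of `f_high` (default 0.15).
#' @param transit_cap Maximum frames allowed for the low-to-high transit
#'   (default 20); slower rises are discarded as compound events.
#' @param pad_before Context frames kept before each event's aligned start
#'   (default 5), so the baseline plateau is represented in the average.
#' @param min_events Minimum number of qualifying events (default 5).
#' @return An `elongation_estimate` list: `w_steps`, `w_seconds`, `f_high`,
#'   `f_low`, `n_events`, `averaged_event`, `breakpoints`.
#' @export
estimate_elongation_time <- function(traces, dt, f_high_q = 0.85,
                                     f_low_frac = 0.15, transit_cap = 20,
                                     pad_before = 5, min_events = 5) {
  if (is.data.frame(traces)) traces <- trace_list(traces)
  pool <- unlist(traces, use.names = FALSE)
  f_high <- unname(quantile(pool, f_high_q))
  f_low <- f_low_frac * f_high
  if (f_low >= f_high) {
    abort_param(
      "no usable low-to-high events: intensity thresholds are degenerate (flat traces)")
  }

  events <- list()
  for (f in traces) {
    n <- length(f)
    hi_cross <- which(f >= f_high & c(-Inf, head(f, -1)) < f_high)
    starts <- integer(0)
    for (t_hi in hi_cross) {
      lows <- which(f[seq_len(t_hi)] <= f_low)
      if (length(lows) == 0) next
      t_lo <- max(lows)
      if (t_hi - t_lo <= transit_cap && !(t_lo %in% starts)) {
        starts <- c(starts, t_lo)
      }
    }
    for (t_lo in starts) {
      idx <- (t_lo - pad_before):(t_lo + transit_cap)
      vals <- rep(NA_real_, length(idx))
      ok <- idx >= 1 & idx <= n
      vals[ok] <- f[idx[ok]]
      events[[length(events) + 1]] <- vals
    }
  }
  if (length(events) < min_events) {
    abort_param(sprintf(
      "only %d low-to-high events found (need >= %d); simulate longer or more traces",
      length(events), min_events))
  }
  ev <- do.call(rbind, events)
  avg <- colMeans(ev, na.rm = TRUE)
  avg <- avg[is.finite(avg)]

  fit <- piecewise3_linear(avg)
  # baseline level at the last pre-ramp frame, plateau level at the first
  # plateau frame (from the fitted segment lines, so a decaying plateau --
  # bursts ending inside the averaging window -- does not bias the level)
  low_level <- fit$seg1$intercept + fit$seg1$slope * fit$a
  high_level <- fit$seg3$intercept + fit$seg3$slope * (fit$b + 1)
  # slope from the ramp interior: the first/last ramp frame mix plateau and
  # ramp across events (alignment jitter), diluting the edge increments
  slope <- fit$seg2$slope
  if (fit$b - fit$a >= 5) {
    xs <- (fit$a + 2):(fit$b - 1)
    sl <- stats::cov(xs, avg[xs]) / stats::var(xs)
    if (is.finite(sl) && sl > 0) slope <- sl
  }
  if (slope <= 0 || high_level <= low_level) {
    abort_param("averaged event has no rising ramp; cannot estimate elongation")
  }
  w_steps <- max(1L, as.integer(round((high_level - low_level) / slope)))
  structure(
    list(w_steps = w_steps, w_seconds = w_steps * dt,
         f_high = f_high, f_low = f_low, n_events = length(events),
         averaged_event = avg,
         breakpoints = c(ramp_start = fit$a + 1L, plateau_start = fit$b + 1L)),
    class = "elongation_estimate"
  )
}
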