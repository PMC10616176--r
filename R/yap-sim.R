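# Synthetic pulsatile nuclear-YAP traces with a stable MCP reference
# channel, emulating endogenously tagged live-imaging cohorts: ~1.5-fold
# Gaussian-shaped pulses of ~2.5 h FWHM on a positive baseline, with
# multiplicative lognormal noise and optional linear drift. The noise is
# temporally correlated by default (AR(1) in log space): denoised
# median-nuclear-intensity traces fluctuate slowly, and only slow noise is
# compatible with the MCP rolling-SD quality filter the detection pipeline
# applies (frame-independent noise of the same magnitude would reject
# every track).

#' Parameters for the pulsatile nuclear-YAP trace generator
#'
#' @param baseline Mean nuclear level (a.u.).
#' @param amp_fold Mean pulse peak as fold over baseline (>= 1).
#' @param amp_sd SD of the per-pulse fold (truncated below at 1.05).
#' @param duration_h Mean pulse FWHM in hours.
#' @param duration_sd_h SD of the per-pulse FWHM (truncated below at 0.5 h).
#' @param pulse_rate Expected number of pulses per trace (Poisson).
#' @param noise_cv Multiplicative lognormal noise CV per frame.
#' @param noise_tau_min Correlation time of the noise in minutes (default
#'   120, emulating slow optical/biological fluctuation in denoised
#'   traces); 0 gives frame-independent noise.
#' @param drift Linear bleach slope per frame (signal is multiplied by
#'   `1 + drift * frame`; use small negative values for bleaching).
#' @param mcp_level Constant nuclear reference (MCP) level (a.u.).
#' @param dt_min Sampling interval in minutes.
#' @return An object of class `yap_pulse_params`.
#' @export
yap_pulse_params <- function(baseline = 100, amp_fold = 1.5, amp_sd = 0.1,
                             duration_h = 2.5, duration_sd_h = 0.3,
                             pulse_rate = 1, noise_cv = 0.05,
                             noise_tau_min = 120, drift = 0,
                             mcp_level = 100, dt_min = 10) {
  if (amp_fold < 1) abort_param("amp_fold must be >= 1")
  if (duration_h <= 0) abort_param("duration_h must be > 0")
  if (noise_cv < 0) abort_param("noise_cv must be >= 0")
  if (dt_min <= 0) abort_param("dt_min must be > 0")
  structure(
    list(baseline = baseline, amp_fold = amp_fold, amp_sd = amp_sd,
         duration_h = duration_h, duration_sd_h = duration_sd_h,
         pulse_rate = pulse_rate, noise_cv = noise_cv,
         noise_tau_min = noise_tau_min, drift = drift,
         mcp_level = mcp_level, dt_min = dt_min),
    class = "yap_pulse_params"
  )
}

# multiplicative lognormal noise with unit mean; AR(1) in log space when
# tau > 0, iid otherwise
lognormal_noise <- function(n, cv, dt_min, tau_min) {
  if (cv == 0) {
    return(rep(1, n))
  }
  s <- sqrt(log(1 + cv^2))
  z <- if (tau_min > 0) {
    phi <- exp(-dt_min / tau_min)
    e <- rnorm(n, 0, s * sqrt(1 - phi^2))
    z <- numeric(n)
    z[1] <- rnorm(1, 0, s)
    for (t in seq_len(n - 1L)) z[t + 1L] <- phi * z[t] + e[t + 1L]
    z
  } else {
    rnorm(n, 0, s)
  }
  exp(z - s^2 / 2)
}

#' Simulate a cohort of two-channel nuclear traces (YAP + MCP reference)
#'
#' YAP channel: `baseline * (1 + sum of Gaussian pulses) * noise * drift`;
#' MCP channel: `mcp_level * noise * drift`. Per-cell pulse counts are
#' Poisson(`pulse_rate`), pulse centers uniform over the trace. Ground truth
#' records every pulse's center, fold and FWHM.
#'
#' @param params A [yap_pulse_params()] object.
#' @param n_cells Number of cells.
#' @param hours Trace length in hours.
#' @param seed Master seed.
#' @return List with `traces` (tibble: `cell_id`, `frame`, `t_s`, `yap_au`,
#'   `mcp_au`) and `ground_truth` (per-cell pulse tables).
#' @export
simulate_yap_cohort <- function(params, n_cells, hours, seed) {
  stopifnot(inherits(params, "yap_pulse_params"))
  if (n_cells < 1) abort_param("n_cells must be >= 1")
  n <- floor(hours * 60 / params$dt_min) + 1L
  t_h <- (seq_len(n) - 1L) * params$dt_min / 60
  fwhm_to_sd <- 1 / (2 * sqrt(2 * log(2)))
  gt <- vector("list", n_cells)
  traces <- purrr::map_dfr(seq_len(n_cells), function(i) {
    with_seed(derive_seed(seed, "yapcell", i), {
      k <- rpois(1, params$pulse_rate)
      centers <- sort(runif(k, 0, max(t_h)))
      folds <- pmax(1.05, rnorm(k, params$amp_fold, params$amp_sd))
      fwhms <- pmax(0.5, rnorm(k, params$duration_h, params$duration_sd_h))
      shape <- rep(0, n)
      for (j in seq_len(k)) {
        sdj <- fwhms[j] * fwhm_to_sd
        shape <- shape + (folds[j] - 1) * exp(-(t_h - centers[j])^2 / (2 * sdj^2))
      }
      drift_f <- 1 + params$drift * (seq_len(n) - 1L)
      yap <- params$baseline * (1 + shape) *
        lognormal_noise(n, params$noise_cv, params$dt_min, params$noise_tau_min) *
        drift_f
      mcp <- params$mcp_level *
        lognormal_noise(n, params$noise_cv, params$dt_min, params$noise_tau_min) *
        drift_f
      gt[[i]] <<- tibble::tibble(
        cell_id = sprintf("cell_%03d", i),
        pulse_center_h = centers, fold = folds, fwhm_h = fwhms
      )
      tibble::tibble(
        cell_id = sprintf("cell_%03d", i),
        frame = seq_len(n) - 1L,
        t_s = (seq_len(n) - 1L) * params$dt_min * 60,
        yap_au = yap, mcp_au = mcp
      )
    })
  })
  list(
    traces = traces,
    ground_truth = list(
      params = unclass(params),
      pulses = dplyr::bind_rows(gt)
    )
  )
}
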