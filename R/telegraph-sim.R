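# Two-state (telegraph) promoter simulation and MS2 readout.
#
# The promoter switches OFF <-> ON with rates k_on, k_off (1/min) and loads
# polymerases at rate r (1/min) while ON. A polymerase contributes full
# fluorescence for exactly w sampling steps (the elongation window), so the
# noiseless signal is a trailing boxcar convolution of the promoter state.

#' Telegraph promoter parameters
#'
#' @param k_on Promoter activation rate (1/min).
#' @param k_off Promoter inactivation rate (1/min).
#' @param r Polymerase initiation rate while ON (polymerases/min).
#' @param w Elongation window in sampling steps (integer >= 1).
#' @param dt Sampling interval in seconds.
#' @param sigma_noise Additive Gaussian measurement noise SD (a.u.).
#' @param calib Fluorescence per polymerase (a.u.); the saturated noiseless
#'   signal is `calib * r * (dt/60) * w`.
#' @return An object of class `promoter_params`.
#' @export
promoter_params <- function(k_on, k_off, r, w, dt,
                            sigma_noise = 0, calib = 1) {
  if (!all(is.finite(c(k_on, k_off, r, sigma_noise, calib)))) {
    abort_param("promoter rates, noise and calibration must be finite")
  }
  if (k_on < 0 || k_off < 0 || r < 0 || sigma_noise < 0) {
    abort_param("k_on, k_off, r and sigma_noise must be >= 0")
  }
  if (w < 1 || w != round(w)) abort_param("w must be an integer >= 1")
  if (dt <= 0) abort_param("dt must be > 0")
  structure(
    list(k_on = k_on, k_off = k_off, r = r, w = as.integer(w), dt = dt,
         sigma_noise = sigma_noise, calib = calib),
    class = "promoter_params"
  )
}

#' Per-step transition matrix of the telegraph promoter
#'
#' Exact matrix exponential of the 2x2 rate matrix over one sampling step:
#' with `s = k_on + k_off` and `e = exp(-s * dt_min)`,
#' `P(OFF->ON) = k_on/s * (1 - e)` and `P(ON->OFF) = k_off/s * (1 - e)`.
#' Rows are the current state (OFF, ON).
#'
#' @param k_on,k_off Switching rates (1/min).
#' @param dt Step length in seconds.
#' @return 2x2 row-stochastic matrix.
#' @export
promoter_step_matrix <- function(k_on, k_off, dt) {
  s <- k_on + k_off
  dt_min <- dt / 60
  if (s == 0) {
    return(diag(2))
  }
  e <- exp(-s * dt_min)
  p01 <- k_on / s * (1 - e)
  p10 <- k_off / s * (1 - e)
  matrix(c(1 - p01, p10, p01, 1 - p10), nrow = 2,
         dimnames = list(c("OFF", "ON"), c("OFF", "ON")))
}

promoter_stationary <- function(k_on, k_off) {
  s <- k_on + k_off
  if (s == 0) c(OFF = 0.5, ON = 0.5) else c(OFF = k_off / s, ON = k_on / s)
}

#' Simulate a telegraph promoter state path
#'
#' Discrete-time simulation with per-step transition probabilities given by
#' the exact two-state matrix exponential over `dt`. The initial state is
#' drawn from the stationary distribution (or fixed via `init`).
#'
#' @param params A [promoter_params()] object.
#' @param n_steps Number of sampling steps (>= 1).
#' @param seed Integer seed.
#' @param init `"stationary"` (default), `"off"`, or `"on"`.
#' @return Integer vector of length `n_steps` over `{0, 1}` (0 = OFF).
#' @export
simulate_promoter_path <- function(params, n_steps, seed,
                                   init = c("stationary", "off", "on")) {
  stopifnot(inherits(params, "promoter_params"))
  if (n_steps < 1) abort_param("n_steps must be >= 1")
  init <- match.arg(init)
  A <- promoter_step_matrix(params$k_on, params$k_off, params$dt)
  pi0 <- promoter_stationary(params$k_on, params$k_off)
  with_seed(seed, {
    u <- runif(n_steps)
    s <- integer(n_steps)
    s[1] <- switch(init,
      stationary = as.integer(u[1] < pi0["ON"]),
      off = 0L,
      on = 1L
    )
    if (init == "stationary" && n_steps >= 1) {
      # u[1] consumed by the initial draw; draw fresh uniforms for steps
      u <- c(u[-1], runif(1))
    }
    p_on <- A[, "ON"] # P(next = ON | current)
    for (t in seq_len(n_steps - 1L)) {
      s[t + 1L] <- as.integer(u[t] < p_on[s[t] + 1L])
    }
    s
  })
}

#' Render an MS2 fluorescence trace from a promoter path
#'
#' `F(t) = calib * r * (dt/60) * sum_{i=0..w-1} s(t - i) + N(0, sigma_noise)`,
#' with window entries before the first frame treated as OFF. The noiseless
#' signal is bounded in `[0, calib * r * (dt/60) * w]`.
#'
#' @param states Binary state vector from [simulate_promoter_path()].
#' @param params A [promoter_params()] object.
#' @param seed Seed for the measurement noise (ignored when
#'   `sigma_noise = 0`).
#' @param ramp If `TRUE`, each polymerase's contribution builds up linearly
#'   over the window (loop build-up during transit); default `FALSE` matches
#'   the compound-emission model used for inference.
#' @return Numeric fluorescence vector, same length as `states`.
#' @export
render_ms2_trace <- function(states, params, seed = NULL, ramp = FALSE) {
  stopifnot(inherits(params, "promoter_params"))
  w <- params$w
  if (w > length(states)) abort_param("elongation window w exceeds trace length")
  load_per_step <- params$calib * params$r * (params$dt / 60)
  # with ramp on, a polymerase of age a contributes (a+1)/w of full intensity
  kern <- if (ramp) seq_len(w) / w else rep(1, w)
  f <- as.numeric(stats::filter(c(rep(0, w - 1), states), kern, sides = 1))
  f <- f[w:(w + length(states) - 1L)] * load_per_step
  if (params$sigma_noise > 0) {
    if (is.null(seed)) abort_param("seed required when sigma_noise > 0")
    f <- f + with_seed(seed, rnorm(length(f), 0, params$sigma_noise))
  }
  f
}

#' Saturated (full-window) noiseless MS2 level for a parameter set
#' @param params A [promoter_params()] object.
#' @return `calib * r * (dt/60) * w`.
#' @export
ms2_saturation <- function(params) {
  params$calib * params$r * (params$dt / 60) * params$w
}

#' Simulate a cohort of MS2 traces
#'
#' Independent cells with per-cell sub-seeds derived deterministically from
#' the master seed, returned in the long trace schema together with the
#' ground-truth promoter paths.
#'
#' @param params A [promoter_params()] object.
#' @param n_cells Number of cells (>= 1).
#' @param n_steps Steps per cell.
#' @param seed Master seed.
#' @inheritParams simulate_promoter_path
#' @return A list with `traces` (tibble: `cell_id`, `frame`, `t_s`,
#'   `ms2_au`) and `ground_truth` (list: params and per-cell state paths).
#' @export
simulate_trace_cohort <- function(params, n_cells, n_steps, seed,
                                  init = "stationary") {
  if (n_cells < 1) abort_param("n_cells must be >= 1")
  cells <- purrr::map(seq_len(n_cells), function(i) {
    s <- simulate_promoter_path(params, n_steps,
                                seed = derive_seed(seed, "path", i),
                                init = init)
    f <- render_ms2_trace(s, params, seed = derive_seed(seed, "noise", i))
    list(states = s, ms2 = f)
  })
  traces <- purrr::map_dfr(seq_len(n_cells), function(i) {
    tibble::tibble(
      cell_id = sprintf("cell_%03d", i),
      frame = seq_len(n_steps) - 1L,
      t_s = (seq_len(n_steps) - 1L) * params$dt,
      ms2_au = cells[[i]]$ms2
    )
  })
  list(
    traces = traces,
    ground_truth = list(
      params = unclass(params),
      states = purrr::map(cells, "states")
    )
  )
}
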