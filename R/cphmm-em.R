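# EM fitting of burst parameters from MS2 trace cohorts, bootstrap
# uncertainty with scaled-MAD outlier rejection, and helpers shared by the
# burst-inference workflow.
#
# Reported parameters: burst frequency = k_on (1/min), burst duration =
# 1/k_off (min; the only duration-dimensioned quantity of the model), burst
# amplitude = initiation rate r (polymerases/min given the calibration, or
# a.u./min at calib = 1).

#' Convert a long trace table into a list of numeric traces
#' @param traces Long table (`cell_id`, `ms2_au`, ordered by frame).
#' @param column Intensity column (default `ms2_au`).
#' @return Named list of numeric vectors.
#' @export
trace_list <- function(traces, column = "ms2_au") {
  split(traces[[column]], traces$cell_id)
}

# relabel so that ON is the higher-emission promoter state (resolves the
# OFF/ON label symmetry of the compound model)
canonicalize_fit <- function(A, nu, b, w) {
  if (nu >= 0) {
    return(list(A = A, nu = nu, b = b))
  }
  list(A = A[2:1, 2:1], nu = -nu, b = b + nu * w)
}

#' Fit burst parameters by EM over the compound-state HMM
#'
#' E-step by scaled forward-backward over the `2^w` register states;
#' M-step in closed form: the per-step promoter matrix from expected
#' transition counts, the emission gain/offset by weighted regression of
#' emissions on the register ON-count, the initial register distribution
#' from the expected first-frame posterior. Rates come from the matrix
#' logarithm of the fitted per-step matrix (exact embedding, not the
#' small-`dt` approximation). The best of `n_starts` random
#' initializations (each run for `burnin_iter` iterations) is continued to
#' convergence.
#'
#' @param traces List of numeric traces (see [trace_list()]) or a long
#'   table.
#' @param w Elongation window (steps).
#' @param dt Step in seconds.
#' @param n_starts Random initializations (default 5).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter Maximum EM iterations after burn-in (default 500).
#' @param burnin_iter Iterations per random start before selection.
#' @param pin_b If `TRUE`, the basal emission offset is fixed at 0.
#' @param calib Fluorescence per polymerase (a.u.) used to express the
#'   amplitude in polymerases/min; at the default 1 the amplitude is in
#'   a.u. per minute.
#' @param seed Seed for the random starts.
#' @return A `burst_params` list: `frequency` (1/min), `duration` (min),
#'   `amplitude`, `k_on`, `k_off`, `r`, `nu`, `b`, `sigma`, `A`, `loglik`,
#'   `loglik_path`, `n_iter`, `degenerate`.
#' @export
em_fit <- function(traces, w, dt, n_starts = 5, tol = 1e-6, max_iter = 500,
                   burnin_iter = 25, pin_b = FALSE, calib = 1, seed = 1) {
  if (is.data.frame(traces)) traces <- trace_list(traces)
  traces <- unname(traces)
  if (length(traces) == 0) abort_param("no traces supplied")
  fall <- unlist(traces)
  if (!all(is.finite(fall))) abort_param("traces must be finite")
  M <- 2^w

  estep_all <- function(A, init, nu, b, sigma) {
    acc <- list(loglik = 0, counts = matrix(0, 2, 2), gamma1 = numeric(M),
                W = 0, Sc = 0, Scc = 0, SF = 0, ScF = 0, SFF = 0)
    for (f in traces) {
      r <- cphmm_estep_cpp(f, w, A, init, nu, b, sigma, want_gamma = FALSE)
      if (!isTRUE(r$ok)) {
        return(NULL)
      }
      acc$loglik <- acc$loglik + r$loglik
      acc$counts <- acc$counts + r$counts
      acc$gamma1 <- acc$gamma1 + r$gamma1
      for (nm in c("W", "Sc", "Scc", "SF", "ScF", "SFF")) {
        acc[[nm]] <- acc[[nm]] + r[[nm]]
      }
    }
    acc
  }

  mstep <- function(acc) {
    C <- acc$counts
    p <- C[1, 2] / max(C[1, 1] + C[1, 2], .Machine$double.eps)
    q <- C[2, 1] / max(C[2, 1] + C[2, 2], .Machine$double.eps)
    p <- min(max(p, 1e-8), 1 - 1e-8)
    q <- min(max(q, 1e-8), 1 - 1e-8)
    A <- matrix(c(1 - p, q, p, 1 - q), 2, 2)
    init <- acc$gamma1 / sum(acc$gamma1)
    if (pin_b) {
      nu <- acc$ScF / max(acc$Scc, .Machine$double.eps)
      b <- 0
    } else {
      det <- acc$W * acc$Scc - acc$Sc^2
      if (abs(det) < 1e-12) { # degenerate occupancy (e.g. all one state)
        nu <- 0
        b <- acc$SF / acc$W
      } else {
        b <- (acc$Scc * acc$SF - acc$Sc * acc$ScF) / det
        nu <- (acc$W * acc$ScF - acc$Sc * acc$SF) / det
      }
    }
    ss <- acc$SFF - 2 * (b * acc$SF + nu * acc$ScF) +
      acc$W * b^2 + 2 * b * nu * acc$Sc + nu^2 * acc$Scc
    sigma <- sqrt(max(ss / acc$W, 1e-12))
    can <- canonicalize_fit(A, nu, b, w)
    if (can$nu != nu) { # relabelled: mirror init and A accordingly
      init <- rev(init) # bitwise complement reverses the state index order
    }
    list(A = can$A, init = init, nu = can$nu, b = can$b, sigma = sigma)
  }

  run_em <- function(par, n_iter) {
    path <- numeric(0)
    for (it in seq_len(n_iter)) {
      acc <- estep_all(par$A, par$init, par$nu, par$b, par$sigma)
      if (is.null(acc)) {
        return(list(par = par, loglik = -Inf, path = path, iters = it))
      }
      path <- c(path, acc$loglik)
      new_par <- mstep(acc)
      converged <- length(path) >= 2 &&
        abs(path[length(path)] - path[length(path) - 1]) <
          tol * abs(path[length(path) - 1])
      par <- new_par
      if (converged) {
        return(list(par = par, loglik = acc$loglik, path = path, iters = it,
                    converged = TRUE))
      }
    }
    list(par = par, loglik = path[length(path)], path = path,
         iters = n_iter, converged = FALSE)
  }

  f_lo <- quantile(fall, 0.05); f_hi <- quantile(fall, 0.95)
  span <- max(f_hi - f_lo, stats::sd(fall), 1e-6)
  starts <- with_seed(seed, {
    purrr::map(seq_len(n_starts), function(i) {
      p <- runif(1, 0.02, 0.3)
      q <- runif(1, 0.02, 0.3)
      nu0 <- span / w * runif(1, 0.5, 2)
      b0 <- if (pin_b) 0 else unname(f_lo) * runif(1)
      list(A = matrix(c(1 - p, q, p, 1 - q), 2, 2),
           init = compound_stationary(matrix(c(1 - p, q, p, 1 - q), 2, 2), w),
           nu = nu0, b = b0,
           sigma = stats::sd(fall) * runif(1, 0.3, 1))
    })
  })

  burns <- purrr::map(starts, run_em, n_iter = burnin_iter)
  best <- burns[[which.max(purrr::map_dbl(burns, "loglik"))]]
  if (!is.finite(best$loglik)) {
    abort_param("all EM starts failed (zero-probability traces)")
  }
  fit <- run_em(best$par, max_iter)
  path <- c(best$path, fit$path)
  par <- fit$par

  # non-embeddable A (p + q >= 1) only arises on degenerate/noise-only
  # data; report a flagged degenerate fit rather than failing
  rates <- tryCatch(rates_from_step_matrix(par$A, dt),
                    error = function(e) list(k_on = NA_real_,
                                             k_off = NA_real_))
  amp <- par$nu / (calib * dt / 60)
  degenerate <- !is.finite(rates$k_on) || !is.finite(rates$k_off) ||
    par$A[1, 2] <= 2e-8 || par$A[2, 1] <= 2e-8 ||
    amp <= 1e-10 || rates$k_on < 1e-10
  structure(
    list(frequency = rates$k_on, duration = 1 / rates$k_off, amplitude = amp,
         k_on = rates$k_on, k_off = rates$k_off, r = amp,
         nu = par$nu, b = par$b, sigma = par$sigma, A = par$A,
         init = par$init, loglik = fit$loglik, loglik_path = path,
         n_iter = length(path), converged = isTRUE(fit$converged),
         degenerate = degenerate, w = w, dt = dt),
    class = "burst_params"
  )
}

#' Remove outliers by the scaled-MAD rule
#'
#' Single pass: drops values more than `3 * 1.4826 * MAD` from the median,
#' where `MAD = median(|x - median|)` and 1.4826 makes the MAD consistent
#' with the Gaussian SD. If the MAD is zero but values differ, only exact
#' median matches are kept (with a warning).
#'
#' @param values Numeric vector (length >= 3).
#' @param n_mad Threshold in scaled MADs (default 3).
#' @return List: `kept` values, `keep` logical index.
#' @export
remove_outliers <- function(values, n_mad = 3) {
  if (length(values) < 3) abort_param("need at least 3 values")
  med <- median(values)
  madv <- median(abs(values - med))
  if (madv == 0) {
    keep <- values == med
    if (!all(keep)) {
      warning("zero MAD with non-identical values: keeping exact median matches")
    }
    return(list(kept = values[keep], keep = keep))
  }
  keep <- abs(values - med) <= n_mad * 1.4826 * madv
  list(kept = values[keep], keep = keep)
}

#' Bootstrap burst-parameter inference
#'
#' Cells are resampled with replacement (the full cohort size per
#' replicate, extended until the time-point floor is met), [em_fit()] is
#' run per replicate, outliers are removed per parameter by the scaled-MAD
#' rule, and the mean and SD over kept replicates are reported.
#'
#' @inheritParams em_fit
#' @param n_boot Number of bootstrap replicates (floor 16, enforced).
#' @param min_timepoints Minimum time points per replicate (floor 1000,
#'   enforced).
#' @param n_starts Random EM starts per replicate (default 3).
#' @param seed Master seed.
#' @param ... Further arguments passed to [em_fit()].
#' @return A `bootstrap_summary` list: `replicates` (tibble of
#'   per-replicate parameters), `mean`, `sd`, `kept` (per-parameter kept
#'   values), `n_boot`, `n_failed`.
#' @export
bootstrap_inference <- function(traces, w, dt, n_boot = 16,
                                min_timepoints = 1000, n_starts = 3,
                                seed = 1, ...) {
  if (n_boot < 16) abort_param("n_boot must be >= 16 (bootstrap floor)")
  if (min_timepoints < 1000) {
    abort_param("min_timepoints must be >= 1000 (per-sample floor)")
  }
  if (is.data.frame(traces)) traces <- trace_list(traces)
  traces <- unname(traces)
  n_cells <- length(traces)
  lens <- lengths(traces)

  reps <- purrr::map(seq_len(n_boot), function(bidx) {
    idx <- with_seed(derive_seed(seed, "boot", bidx), {
      i <- sample.int(n_cells, n_cells, replace = TRUE)
      while (sum(lens[i]) < min_timepoints) {
        i <- c(i, sample.int(n_cells, 1))
      }
      i
    })
    fit <- tryCatch(
      em_fit(traces[idx], w = w, dt = dt, n_starts = n_starts,
             seed = derive_seed(seed, "emstart", bidx), ...),
      error = function(e) NULL
    )
    # a replicate without finite rates carries no usable parameters
    if (!is.null(fit) && !is.finite(fit$frequency)) fit <- NULL
    fit
  })
  failed <- purrr::map_lgl(reps, is.null)
  if (mean(failed) > 0.5) {
    abort_param(sprintf("%d of %d bootstrap replicates failed EM",
                        sum(failed), n_boot))
  }
  reps <- reps[!failed]
  tab <- purrr::map_dfr(seq_along(reps), function(i) {
    tibble::tibble(replicate = i,
                   frequency = reps[[i]]$frequency,
                   duration = reps[[i]]$duration,
                   amplitude = reps[[i]]$amplitude,
                   loglik = reps[[i]]$loglik)
  })
  pars <- c("frequency", "duration", "amplitude")
  kept <- purrr::map(setNames(pars, pars),
                     function(p) remove_outliers(tab[[p]])$kept)
  structure(
    list(replicates = tab,
         kept = kept,
         mean = purrr::map_dbl(kept, mean),
         sd = purrr::map_dbl(kept, sd),
         n_boot = n_boot, n_failed = sum(failed),
         w = w, dt = dt),
    class = "bootstrap_summary"
  )
}
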