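# Compound-state HMM construction and exact inference. The hidden state is
# the promoter's history over the elongation window w (a shift register of
# w binary promoter states), so the Gaussian emission mean is linear in the
# number of ON entries still inside the window.

#' Build a compound-state HMM
#'
#' The per-step promoter matrix is the exact matrix exponential of the
#' two-state rate matrix over `dt`; compound transitions append the new
#' promoter state and drop the oldest; emissions are Gaussian with mean
#' `nu * oncount + b` where `nu = calib * r * dt/60` is the fluorescence
#' contributed by one polymerase-step. The initial compound distribution is
#' the stationary promoter chain propagated through the window.
#'
#' @param k_on,k_off Switching rates (1/min).
#' @param r Initiation rate while ON (polymerases/min).
#' @param sigma Emission SD (a.u., > 0).
#' @param w Window length in steps (`2^w` compound states; capped).
#' @param dt Step in seconds.
#' @param b Basal emission offset (a.u.).
#' @param calib Fluorescence per polymerase (a.u.).
#' @param state_cap Maximum allowed number of compound states (default
#'   `2^12`).
#' @return An object of class `compound_hmm` with elements `w`, `dt`, `A`,
#'   `nu`, `b`, `sigma`, `init`, `oncount`.
#' @export
build_compound_model <- function(k_on, k_off, r, sigma, w, dt, b = 0,
                                 calib = 1, state_cap = 2^12) {
  if (w < 1 || w != round(w)) abort_param("w must be an integer >= 1")
  if (2^w > state_cap) {
    abort_param(sprintf("2^w = %d compound states exceeds the cap (%d)",
                        2^w, state_cap))
  }
  if (sigma <= 0) abort_param("sigma must be > 0")
  A <- promoter_step_matrix(k_on, k_off, dt)
  nu <- calib * r * (dt / 60)
  structure(
    list(w = as.integer(w), dt = dt, A = unname(A), nu = nu, b = b,
         sigma = sigma,
         k_on = k_on, k_off = k_off, r = r, calib = calib,
         init = compound_stationary(unname(A), w),
         oncount = compound_oncount(w)),
    class = "compound_hmm"
  )
}

# number of ON bits in each register state 0..2^w-1
compound_oncount <- function(w) {
  vapply(0:(2^w - 1), function(s) sum(bitwAnd(s, bitwShiftL(1L, 0:(w - 1))) > 0),
         integer(1))
}

# stationary distribution of the compound (shift-register) chain:
# P(s) = pi(oldest bit) * prod of step transitions towards the newest bit
compound_stationary <- function(A, w) {
  p <- A[1, 2]; q <- A[2, 1]
  pi0 <- if (p + q == 0) c(0.5, 0.5) else c(q, p) / (p + q)
  M <- 2^w
  init <- numeric(M)
  for (s in 0:(M - 1)) {
    bits <- bitwAnd(bitwShiftR(s, (w - 1):0), 1L) # oldest ... newest
    pr <- pi0[bits[1] + 1]
    if (w > 1) {
      for (i in seq_len(w - 1)) pr <- pr * A[bits[i] + 1, bits[i + 1] + 1]
    }
    init[s + 1] <- pr
  }
  init
}

# distribution for a register known to be empty before the first frame:
# older bits OFF, newest bit from the stationary promoter distribution
compound_empty_start <- function(A, w) {
  p <- A[1, 2]; q <- A[2, 1]
  pi0 <- if (p + q == 0) c(0.5, 0.5) else c(q, p) / (p + q)
  init <- numeric(2^w)
  init[0 + 1] <- pi0[1]
  init[1 + 1] <- pi0[2]
  init
}

#' Forward-backward inference under a compound-state HMM
#'
#' Numerically scaled recursion; posteriors sum to 1 at every time point.
#'
#' @param trace Numeric fluorescence vector.
#' @param model A [build_compound_model()] object.
#' @return List: `loglik`, `posterior` (T x 2^w matrix over compound
#'   states), `p_on` (posterior probability that the current promoter state
#'   is ON at each time), `ok` (`FALSE` with `loglik = -Inf` for a
#'   zero-probability trace).
#' @export
forward_backward <- function(trace, model) {
  stopifnot(inherits(model, "compound_hmm"))
  if (!all(is.finite(trace))) abort_param("trace must be finite")
  res <- cphmm_estep_cpp(trace, model$w, model$A, model$init,
                         model$nu, model$b, model$sigma, want_gamma = TRUE)
  if (!isTRUE(res$ok)) {
    return(list(loglik = -Inf, posterior = NULL, p_on = NULL, ok = FALSE))
  }
  post <- res$gamma
  cur_on <- bitwAnd(0:(2^model$w - 1), 1L) == 1L
  list(loglik = res$loglik, posterior = post,
       p_on = rowSums(post[, cur_on, drop = FALSE]), ok = TRUE)
}

#' Continuous-time rates from a per-step transition matrix
#'
#' Exact embedding via the 2x2 matrix logarithm: for per-step
#' probabilities `p = P(OFF->ON)`, `q = P(ON->OFF)` the generator rates are
#' `k_on = p * lambda / (p + q)` and `k_off = q * lambda / (p + q)` with
#' `lambda = -log(1 - p - q)`, divided by the step length.
#'
#' @param A 2x2 row-stochastic matrix (rows OFF, ON).
#' @param dt Step in seconds.
#' @return List with `k_on`, `k_off` in 1/min.
#' @export
rates_from_step_matrix <- function(A, dt) {
  p <- A[1, 2]; q <- A[2, 1]
  s <- p + q
  dt_min <- dt / 60
  if (s == 0) {
    return(list(k_on = 0, k_off = 0))
  }
  if (s >= 1) {
    abort_param("step matrix is not embeddable (p + q >= 1): no valid rates")
  }
  lambda <- -log(1 - s)
  list(k_on = p / s * lambda / dt_min, k_off = q / s * lambda / dt_min)
}
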