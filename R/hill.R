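# Four-parameter Hill (sigmoidal) dose-response fitting and IC-quantile
# computation. Repression convention: top plateau at low dose, bottom at
# high dose, IC50 at half repression, Hill exponent n sets switch-likeness.

#' Fit a four-parameter Hill repression curve
#'
#' Least squares of `y = bottom + (top - bottom) / (1 + (x/ic50)^n)` on
#' linear dose. Initialization: plateaus from the dose-extreme deciles,
#' IC50 from the half-range crossing of binned means, `n = 1`; the exponent
#' is bounded in `(0, 10]`.
#'
#' @param dose,response Numeric vectors (same length; dose > 0 for cells
#'   entering the fit, non-positive doses are dropped).
#' @param n_bins Bins used for initialization and the flatness check.
#' @return A `hill_fit` list: `top`, `bottom`, `ic50`, `n`, `rsq`,
#'   `n_cells`.
#' @export
fit_hill <- function(dose, response, n_bins = 10) {
  keep <- is.finite(dose) & is.finite(response) & dose > 0
  x <- dose[keep]; y <- response[keep]
  if (length(unique(round(log10(x), 2))) < 6) {
    abort_param("need >= 6 distinct dose levels spanning the transition")
  }
  # binned means on log dose for initialization and the flatness check
  br <- quantile(log(x), seq(0, 1, length.out = n_bins + 1))
  br[1] <- br[1] - 1e-9
  bins <- cut(log(x), unique(br))
  bm <- tapply(y, bins, mean)
  bse <- tapply(y, bins, function(v) sd(v) / sqrt(length(v)))
  pooled_se <- sqrt(mean(bse^2, na.rm = TRUE))
  if (!is.finite(pooled_se)) pooled_se <- sd(y) / sqrt(length(y))
  if (diff(range(bm, na.rm = TRUE)) < 4 * pooled_se) {
    stop("non_sigmoidal: no transition in the data", call. = FALSE)
  }
  lo_q <- x <= quantile(x, 0.1); hi_q <- x >= quantile(x, 0.9)
  top0 <- mean(y[lo_q]); bottom0 <- mean(y[hi_q])
  mid <- (top0 + bottom0) / 2
  bin_centers <- tapply(x, bins, stats::median)
  ic0 <- bin_centers[which.min(abs(bm - mid))]
  if (!is.finite(ic0) || ic0 <= 0) ic0 <- stats::median(x)
  d <- data.frame(x = x, y = y)
  fit <- minpack.lm::nlsLM(
    y ~ bottom + (top - bottom) / (1 + (x / ic50)^n),
    data = d,
    start = list(top = top0, bottom = bottom0, ic50 = unname(ic0), n = 1),
    lower = c(top = -Inf, bottom = -Inf, ic50 = 1e-12, n = 1e-3),
    upper = c(top = Inf, bottom = Inf, ic50 = Inf, n = 10),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  p <- as.list(coef(fit))
  rsq <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  structure(
    list(top = p$top, bottom = p$bottom, ic50 = p$ic50, n = p$n,
         rsq = rsq, n_cells = length(x)),
    class = "hill_fit"
  )
}

#' Dose achieving q percent of maximal repression
#'
#' Closed form on the fitted curve: `ICq = IC50 * (q / (100 - q))^(1/n)`;
#' the response at `ICq` is `top - (q/100) * (top - bottom)`.
#'
#' @param fit A [fit_hill()] object (or any list with `ic50` and `n`).
#' @param q Percent repression, in (0, 100).
#' @return Dose value.
#' @export
icq <- function(fit, q) {
  if (q <= 0 || q >= 100) abort_param("q must be in (0, 100)")
  fit$ic50 * (q / (100 - q))^(1 / fit$n)
}
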