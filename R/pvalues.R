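# Cross-bootstrap fold-change p-values: the fraction of all pairwise
# bootstrap fold estimates that contradict the observed trend. One-sided;
# ties count against significance.

#' One-sided cross-bootstrap fold-change p-value
#'
#' For every pair (a in `boot_a`, b in `boot_b`) the fold `b / a` is
#' computed (`|boot_a| * |boot_b|` folds in total). For
#' `direction = "increase"` the p-value is the fraction of folds <= 1; for
#' `"decrease"` the fraction >= 1. Exact ties count against the trend
#' (conservative).
#'
#' @param boot_a Bootstrap values of the reference group (denominator).
#' @param boot_b Bootstrap values of the comparison group (numerator).
#' @param direction `"increase"` (default) or `"decrease"`.
#' @return A `fold_change_test` list: `p`, `n_fold`, `direction`,
#'   `fold_mean`.
#' @export
fold_change_pvalue <- function(boot_a, boot_b,
                               direction = c("increase", "decrease")) {
  direction <- match.arg(direction)
  if (length(boot_a) == 0 || length(boot_b) == 0) {
    abort_param("both bootstrap sets must be non-empty")
  }
  if (any(boot_a == 0)) abort_param("zero denominator in boot_a")
  folds <- as.vector(outer(boot_b, boot_a, `/`))
  p <- if (direction == "increase") mean(folds <= 1) else mean(folds >= 1)
  structure(
    list(p = p, n_fold = length(folds), direction = direction,
         fold_mean = mean(folds)),
    class = "fold_change_test"
  )
}
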