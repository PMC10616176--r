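# Inference-group assembly: traces are pooled by experimental condition,
# by nuclear YAP level (tertiles or fixed bins), or by time window relative
# to an optogenetic perturbation (traces are split at window edges).

#' Split traces into inference groups
#'
#' @param traces Long trace table (`cell_id`, `frame`, `t_s`, `ms2_au`).
#' @param metadata Per-cell table: `cell_id` plus `condition` (condition
#'   scheme) or `yap_au` (yap scheme).
#' @param scheme `"condition"`, `"yap"` (tertiles or `breaks`), or
#'   `"time"` (windows in minutes; traces split at window edges).
#' @param breaks For `"yap"`: optional numeric cut points (otherwise
#'   tertiles, labelled low/mid/high).
#' @param windows For `"time"`: named list of `c(start_min, end_min)`
#'   half-open intervals, default dark `[0, 45)`, lit_early `[45, 240)`,
#'   lit_late `[240, Inf)`.
#' @return Named list of long trace tables.
#' @export
group_traces <- function(traces, metadata = NULL,
                         scheme = c("condition", "yap", "time"),
                         breaks = NULL,
                         windows = list(dark = c(0, 45),
                                        lit_early = c(45, 240),
                                        lit_late = c(240, Inf))) {
  scheme <- match.arg(scheme)
  if (scheme == "condition") {
    if (is.null(metadata) || !"condition" %in% names(metadata)) {
      abort_param("condition scheme requires metadata with a condition column")
    }
    joined <- dplyr::inner_join(traces, metadata[, c("cell_id", "condition")],
                                by = "cell_id")
    return(split(dplyr::select(joined, -"condition"), joined$condition))
  }
  if (scheme == "yap") {
    if (is.null(metadata) || !"yap_au" %in% names(metadata)) {
      abort_param("yap scheme requires metadata with a yap_au column")
    }
    if (is.null(breaks)) {
      qs <- quantile(metadata$yap_au, c(1 / 3, 2 / 3))
      breaks <- c(-Inf, qs, Inf)
    }
    labels <- if (length(breaks) == 4) c("low", "mid", "high") else NULL
    metadata$.bin <- cut(metadata$yap_au, breaks = breaks, labels = labels,
                         include.lowest = TRUE)
    joined <- dplyr::inner_join(traces, metadata[, c("cell_id", ".bin")],
                                by = "cell_id")
    return(split(dplyr::select(joined, -".bin"), joined$.bin, drop = TRUE))
  }
  # time scheme: assign each frame to its window; a trace contributes its
  # overlapping fragment to each window
  if (!"t_s" %in% names(traces)) abort_param("time scheme requires a t_s column")
  out <- purrr::imap(windows, function(wd, nm) {
    t_min <- traces$t_s / 60
    dplyr::filter(traces, t_min >= wd[1] & t_min < wd[2])
  })
  out[purrr::map_int(out, nrow) > 0]
}
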