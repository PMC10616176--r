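# Readers/writers for the pipeline's plain-text interchange formats.

#' Write / read a long trace table as CSV
#'
#' Schema: `cell_id, frame, t_s, <channel columns>` (0-based frames, time
#' in seconds). Ground truth travels as a sidecar JSON next to the CSV.
#'
#' @param traces Long trace table.
#' @param path CSV path.
#' @param ground_truth Optional list written to `<path>.truth.json`.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(traces, path, ground_truth = NULL) {
  validate_trace_table(traces)
  readr::write_csv(traces, path)
  if (!is.null(ground_truth)) {
    jsonlite::write_json(ground_truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  traces <- readr::read_csv(path, show_col_types = FALSE)
  validate_trace_table(traces)
  truth_path <- paste0(path, ".truth.json")
  truth <- if (file.exists(truth_path)) {
    jsonlite::read_json(truth_path, simplifyVector = TRUE)
  } else {
    NULL
  }
  if (is.null(truth)) traces else structure(traces, ground_truth = truth)
}
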