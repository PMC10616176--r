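#!/usr/bin/env Rscript
# Nuclear-YAP pulse analysis: normalization, QC, pulse detection and cohort
# statistics on the simulated pulsing cohort, plus the false-positive rate
# on the pulse-free control. Mirrors the live-imaging quantification:
# per-frame cohort-mean normalization, per-trace minimum normalization,
# 3-frame end trimming, 10-point MCP rolling-SD filter at 0.05, >= 10 h
# track filter, rolling-mean(2) smoothing, prominence 0.25 / height 1.3.
#
# Reads results/data/, writes results/pulses/.

suppressPackageStartupMessages(library(yapburst))
data_dir <- "results/data"
out <- "results/pulses"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

pulsing <- read_trace_csv(file.path(data_dir, "yap_pulsing.csv"))
res <- detect_yap_pulses(pulsing, dt_min = 10)
passing <- res$qc$cell_id[res$qc$qc_status == "pass"]
summary <- summarize_pulsing(res$calls, passing)

control <- read_trace_csv(file.path(data_dir, "yap_control.csv"))
rc <- detect_yap_pulses(control, dt_min = 10)
pass_c <- rc$qc$cell_id[rc$qc$qc_status == "pass"]
fpr <- false_positive_rate(rc$calls, pass_c)

readr::write_csv(dplyr::left_join(res$calls, res$qc, by = "cell_id"),
                 file.path(out, "pulse_calls.csv"))
jsonlite::write_json(
  c(summary, list(false_positive_rate = fpr,
                  n_control = length(pass_c))),
  file.path(out, "pulse_summary.json"),
  auto_unbox = TRUE, digits = NA, pretty = TRUE)

message(sprintf(
  "analyzed %d cells (%d rejected by QC): %.0f%% pulsing, amplitude %.2f-fold, duration %.2f h",
  summary$n_cells, nrow(res$qc) - summary$n_cells,
  100 * summary$fraction_pulsing, summary$amplitude$mean,
  summary$duration_h$mean))
message(sprintf("control false-positive rate: %.1f%% of %d cells",
                100 * fpr, length(pass_c)))
message(
  "note: fold-over-minimum amplitudes carry a systematic ~+10% inflation ",
  "under 5% trace noise (see the methods vignette)")
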