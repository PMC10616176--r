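# Nuclear-signal pulse detection pipeline: cohort normalization (per-frame
# cohort mean, then per-trace minimum), end trimming, track-length and
# MCP-stability QC, rolling-mean smoothing and prominence/height peak
# detection, with cohort summaries and a control false-positive rate.

#' Quality-control parameters for nuclear trace filtering
#'
#' @param trim_frames Frames removed from each trace end (mitosis guard).
#' @param mcp_std_window Rolling-SD window on the normalized MCP trace
#'   (time points).
#' @param mcp_std_threshold Exclusion threshold on the MCP rolling SD.
#' @param min_track_h Minimum track length after trimming (hours).
#' @return An object of class `qc_params`.
#' @export
qc_params <- function(trim_frames = 3, mcp_std_window = 10,
                      mcp_std_threshold = 0.05, min_track_h = 10) {
  if (mcp_std_window < 2) abort_param("mcp_std_window must be >= 2")
  if (trim_frames < 0 || mcp_std_threshold < 0 || min_track_h < 0) {
    abort_param("qc parameters must be >= 0")
  }
  structure(list(trim_frames = as.integer(trim_frames),
                 mcp_std_window = as.integer(mcp_std_window),
                 mcp_std_threshold = mcp_std_threshold,
                 min_track_h = min_track_h),
            class = "qc_params")
}

#' Peak-detection parameters
#'
#' Thresholds apply to the min-normalized, rolling-mean-smoothed trace:
#' a reported peak is a local maximum with prominence >= `prominence` and
#' absolute height >= `height`.
#'
#' @param smooth_window Trailing rolling-mean window (time points).
#' @param prominence Minimum peak prominence.
#' @param height Minimum absolute peak height.
#' @return An object of class `peak_params`.
#' @export
peak_params <- function(smooth_window = 2, prominence = 0.25, height = 1.3) {
  if (smooth_window < 1) abort_param("smooth_window must be >= 1")
  if (prominence <= 0 || height <= 0) {
    abort_param("prominence and height must be > 0")
  }
  structure(list(smooth_window = as.integer(smooth_window),
                 prominence = prominence, height = height),
            class = "peak_params")
}

#' Trim frames from both ends of every trace
#'
#' Removes the first and last `trim_frames` frames per cell (guards against
#' mitosis-adjacent frames). Applied before normalization so trimmed frames
#' do not enter cohort means.
#'
#' @param traces Long trace table with `cell_id` and `frame`.
#' @param trim_frames Frames to drop at each end.
#' @return Trimmed table.
#' @export
trim_traces <- function(traces, trim_frames = 3) {
  if (trim_frames == 0) return(traces)
  traces |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::filter(dplyr::row_number() > trim_frames,
                  dplyr::row_number() <= dplyr::n() - trim_frames) |>
    dplyr::ungroup()
}

#' Normalize a two-channel trace cohort
#'
#' Step 1: each channel at each frame is divided by the cohort mean of that
#' channel at that frame (corrects shared bleaching/drift). Step 2: each
#' trace is divided by its own minimum, so every normalized trace has
#' minimum 1 and is invariant to per-cell gain.
#'
#' @param traces Long table with `cell_id`, `frame` and the channel columns.
#' @param channels Channel column names (default `yap_au`, `mcp_au`).
#' @return The table with channels replaced by their normalized values.
#' @export
normalize_cohort <- function(traces, channels = c("yap_au", "mcp_au")) {
  channels <- intersect(channels, names(traces))
  if (length(channels) == 0) abort_param("no channel columns found")
  out <- traces
  # a single-cell cohort degenerates to min-normalization only (dividing a
  # lone trace by itself would flatten it)
  single_cell <- length(unique(traces$cell_id)) < 2
  for (ch in channels) {
    if (single_cell) {
      out$.cmean <- 1
    } else {
      out <- out |>
        dplyr::group_by(.data$frame) |>
        dplyr::mutate(.cmean = mean(.data[[ch]])) |>
        dplyr::ungroup()
    }
    bad <- which(out$.cmean == 0)
    if (length(bad) > 0) {
      abort_param(sprintf("zero cohort mean for %s at frame %d",
                          ch, out$frame[bad[1]]))
    }
    out[[ch]] <- out[[ch]] / out$.cmean
    out$.cmean <- NULL
    out <- out |>
      dplyr::group_by(.data$cell_id) |>
      dplyr::mutate(.tmin = min(.data[[ch]])) |>
      dplyr::ungroup()
    bad <- which(out$.tmin == 0)
    if (length(bad) > 0) {
      abort_param(sprintf("zero trace minimum for %s in cell %s",
                          ch, out$cell_id[bad[1]]))
    }
    out[[ch]] <- out[[ch]] / out$.tmin
    out$.tmin <- NULL
  }
  out
}

rolling_sd <- function(x, window) {
  n <- length(x)
  if (n < window) return(rep(NA_real_, n))
  out <- rep(NA_real_, n)
  for (i in window:n) out[i] <- stats::sd(x[(i - window + 1L):i])
  out
}

#' QC-filter normalized traces
#'
#' Rejects tracks shorter than `min_track_h` and cells whose normalized MCP
#' rolling SD exceeds the threshold anywhere (tracking errors / mitosis).
#' Assumes ends were already trimmed ([trim_traces()]); set
#' `trim_frames > 0` here only if not.
#'
#' @param traces Normalized table from [normalize_cohort()].
#' @param params A [qc_params()] object.
#' @param dt_min Sampling interval in minutes.
#' @param trim_frames Extra end-trimming to apply here (default 0).
#' @return Tibble: `cell_id`, `qc_status` (`pass`, `short_track`,
#'   `mcp_unstable`).
#' @export
qc_filter <- function(traces, params, dt_min, trim_frames = 0) {
  stopifnot(inherits(params, "qc_params"))
  if (trim_frames > 0) traces <- trim_traces(traces, trim_frames)
  has_mcp <- "mcp_au" %in% names(traces)
  traces |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(
      .len_h = (dplyr::n() - 1L) * dt_min / 60,
      .mcp_sd_max = if (has_mcp) {
        suppressWarnings(max(rolling_sd(.data$mcp_au, params$mcp_std_window),
                             na.rm = TRUE))
      } else {
        -Inf
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(
      qc_status = dplyr::case_when(
        .data$.len_h < params$min_track_h ~ "short_track",
        .data$.mcp_sd_max > params$mcp_std_threshold ~ "mcp_unstable",
        TRUE ~ "pass"
      )
    ) |>
    dplyr::select("cell_id", "qc_status")
}

#' Trailing rolling mean (first samples passed through)
#' @param x Numeric vector.
#' @param window Window size in samples.
#' @return Smoothed vector, same length.
#' @export
rolling_mean <- function(x, window) {
  if (window <= 1) return(x)
  out <- as.numeric(stats::filter(x, rep(1 / window, window), sides = 1))
  head_n <- min(window - 1L, length(x))
  out[seq_len(head_n)] <- cumsum(x[seq_len(head_n)]) / seq_len(head_n)
  out
}

# Local maxima by simple neighbor comparison; flat tops yield their middle
# sample. Returns integer indices.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer())
  peaks <- integer()
  i <- 2L
  while (i < n) {
    if (x[i - 1L] < x[i]) {
      i_ahead <- i
      while (i_ahead < n && x[i_ahead + 1L] == x[i]) i_ahead <- i_ahead + 1L
      if (i_ahead < n && x[i_ahead + 1L] < x[i]) {
        peaks <- c(peaks, as.integer(floor((i + i_ahead) / 2)))
        i <- i_ahead
      }
    }
    i <- i + 1L
  }
  peaks
}

# Prominence: height of the peak above the higher of the two flanking
# minima, where each flank extends to the nearest higher point or the trace
# end.
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    lo <- p
    while (lo > 1L && x[lo - 1L] <= x[p]) lo <- lo - 1L
    left_min <- min(x[lo:p])
    hi <- p
    n <- length(x)
    while (hi < n && x[hi + 1L] <= x[p]) hi <- hi + 1L
    right_min <- min(x[p:hi])
    x[p] - max(left_min, right_min)
  }, numeric(1))
}

# Width at half prominence with linear interpolation of the crossings,
# in samples.
peak_width_half_prom <- function(x, peaks, prominences) {
  n <- length(x)
  mapply(function(p, prom) {
    level <- x[p] - prom / 2
    i <- p
    while (i > 1L && x[i - 1L] >= level) i <- i - 1L
    left <- if (i == 1L || x[i] == level) i else {
      i - (level - x[i]) / (x[i - 1L] - x[i])
    }
    j <- p
    while (j < n && x[j + 1L] >= level) j <- j + 1L
    right <- if (j == n || x[j] == level) j else {
      j + (level - x[j]) / (x[j + 1L] - x[j])
    }
    right - left
  }, peaks, prominences)
}

#' Detect pulses in one normalized trace
#'
#' The trace is smoothed with a trailing rolling mean, local maxima are
#' found by neighbor comparison, and peaks passing both the prominence and
#' the absolute-height threshold are reported with their width at half
#' prominence (converted to hours) and amplitude (smoothed peak value, i.e.
#' fold over the trace minimum).
#'
#' @param y Min-normalized signal vector for one cell.
#' @param params A [peak_params()] object.
#' @param dt_min Sampling interval in minutes.
#' @return Tibble: `peak_index`, `peak_time_h`, `duration_h`, `amplitude`,
#'   `prominence`.
#' @export
detect_pulses <- function(y, params, dt_min) {
  stopifnot(inherits(params, "peak_params"))
  if (length(y) < params$smooth_window) {
    abort_param("trace shorter than the smoothing window")
  }
  s <- rolling_mean(y, params$smooth_window)
  peaks <- local_maxima(s)
  if (length(peaks) == 0) {
    return(tibble::tibble(peak_index = integer(), peak_time_h = numeric(),
                          duration_h = numeric(), amplitude = numeric(),
                          prominence = numeric()))
  }
  prom <- peak_prominence(s, peaks)
  keep <- prom >= params$prominence & s[peaks] >= params$height
  peaks <- peaks[keep]
  prom <- prom[keep]
  if (length(peaks) == 0) {
    return(tibble::tibble(peak_index = integer(), peak_time_h = numeric(),
                          duration_h = numeric(), amplitude = numeric(),
                          prominence = numeric()))
  }
  widths <- peak_width_half_prom(s, peaks, prom)
  tibble::tibble(
    peak_index = peaks,
    peak_time_h = (peaks - 1L) * dt_min / 60,
    duration_h = widths * dt_min / 60,
    amplitude = s[peaks],
    prominence = prom
  )
}

#' Run the full pulse pipeline on a raw two-channel cohort
#'
#' Trim ends, normalize (cohort mean then trace minimum), QC-filter, and
#' detect pulses on every passing cell's YAP channel.
#'
#' @param traces Raw long table (`cell_id`, `frame`, `yap_au`, `mcp_au`).
#' @param qc A [qc_params()] object.
#' @param peaks A [peak_params()] object.
#' @param dt_min Sampling interval in minutes.
#' @return List with `calls` (per-peak tibble incl. `cell_id`), `qc`
#'   (per-cell status) and `normalized` (the processed table).
#' @export
detect_yap_pulses <- function(traces, qc = qc_params(), peaks = peak_params(),
                              dt_min) {
  trimmed <- trim_traces(traces, qc$trim_frames)
  norm <- normalize_cohort(trimmed)
  status <- qc_filter(norm, qc, dt_min)
  passing <- status$cell_id[status$qc_status == "pass"]
  empty_calls <- tibble::tibble(cell_id = character(), peak_index = integer(),
                                peak_time_h = numeric(), duration_h = numeric(),
                                amplitude = numeric(), prominence = numeric())
  calls <- if (length(passing) == 0) {
    empty_calls
  } else {
    norm |>
      dplyr::filter(.data$cell_id %in% passing) |>
      dplyr::group_by(.data$cell_id) |>
      dplyr::group_modify(~ detect_pulses(.x$yap_au, peaks, dt_min)) |>
      dplyr::ungroup()
  }
  list(calls = calls, qc = status, normalized = norm)
}

#' Summarize pulsing across a cohort
#'
#' @param calls Peak table from [detect_yap_pulses()] (`cell_id` per peak).
#' @param cells Character vector of all analyzed (QC-passing) cell ids.
#' @return List: `fraction_pulsing`, `n_cells`, `duration_h`
#'   (mean/median/p5/p95), `amplitude` (mean/median/p5/p95).
#' @export
summarize_pulsing <- function(calls, cells) {
  if (length(cells) == 0) abort_param("no analyzed cells supplied")
  qtl <- function(x) {
    if (length(x) == 0) {
      return(list(mean = NA_real_, median = NA_real_,
                  p5 = NA_real_, p95 = NA_real_))
    }
    list(mean = mean(x), median = median(x),
         p5 = unname(quantile(x, 0.05)), p95 = unname(quantile(x, 0.95)))
  }
  pulsing_cells <- unique(calls$cell_id)
  list(
    n_cells = length(cells),
    n_pulsing = length(intersect(pulsing_cells, cells)),
    fraction_pulsing = length(intersect(pulsing_cells, cells)) / length(cells),
    duration_h = qtl(calls$duration_h),
    amplitude = qtl(calls$amplitude)
  )
}

#' False-positive rate on a pulse-free control cohort
#'
#' Fraction of analyzed control cells in which at least one pulse is called.
#'
#' @inheritParams summarize_pulsing
#' @return A single fraction in `[0, 1]`.
#' @export
false_positive_rate <- function(calls, cells) {
  if (length(cells) == 0) abort_param("no analyzed cells supplied")
  length(intersect(unique(calls$cell_id), cells)) / length(cells)
}
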