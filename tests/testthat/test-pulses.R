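test_that("cohort normalization: constants, gain invariance, shared drift", {
  co <- flat_cohort(4, 20)
  norm <- normalize_cohort(co)
  expect_true(all(norm$yap_au == 1) && all(norm$mcp_au == 1))

  # a global gain (e.g. laser power) cancels exactly
  p <- yap_pulse_params(pulse_rate = 1, noise_cv = 0.03)
  raw <- simulate_yap_cohort(p, 6, 12, seed = 1)$traces
  gained <- dplyr::mutate(raw, yap_au = yap_au * 5, mcp_au = mcp_au * 5)
  expect_equal(normalize_cohort(gained)$yap_au, normalize_cohort(raw)$yap_au,
               tolerance = 1e-12)
  # single-cell cohorts degenerate to min-normalization only
  one <- dplyr::filter(raw, cell_id == "cell_001")
  n_one <- normalize_cohort(one)
  expect_equal(n_one$yap_au, one$yap_au / min(one$yap_au), tolerance = 1e-12)

  # shared linear bleach cancels through the per-frame cohort mean
  bleached <- flat_cohort(4, 30) |>
    dplyr::mutate(yap_au = yap_au * (1 - 0.001 * frame),
                  mcp_au = mcp_au * (1 - 0.001 * frame))
  nb <- normalize_cohort(bleached)
  expect_true(all(abs(nb$yap_au - 1) < 1e-12))
})

test_that("normalization errors name the offending frame or cell", {
  co <- flat_cohort(2, 10)
  co$yap_au[co$frame == 3] <- 0
  expect_error(normalize_cohort(co), "frame 3")
  co2 <- flat_cohort(2, 10)
  co2$yap_au[co2$cell_id == "c02" & co2$frame == 5] <- 0
  expect_error(normalize_cohort(co2), "c02")
})

test_that("QC: track length and MCP stability", {
  # 16 h flat track passes
  long <- normalize_cohort(flat_cohort(2, 97))
  st <- qc_filter(long, qc_params(), dt_min = 10)
  expect_true(all(st$qc_status == "pass"))
  # 8 h track rejected as short
  short <- normalize_cohort(flat_cohort(2, 49))
  expect_true(all(qc_filter(short, qc_params(), 10)$qc_status == "short_track"))
  # MCP step mid-track: rolling SD over the step exceeds 0.05 for the
  # stepping cell only (in a cohort large enough that the shared per-frame
  # mean moves little)
  step <- flat_cohort(20, 97)
  step$mcp_au[step$cell_id == "c01" & step$frame >= 48] <- 200
  stn <- normalize_cohort(step)
  sts <- qc_filter(stn, qc_params(), 10)
  expect_equal(sts$qc_status[sts$cell_id == "c01"], "mcp_unstable")
  expect_true(all(sts$qc_status[sts$cell_id != "c01"] == "pass"))
})

test_that("peak detection on canonical traces", {
  pk <- peak_params()
  expect_equal(nrow(detect_pulses(rep(1, 60), pk, 10)), 0)
  # noiseless Gaussian bump, fold 1.5, FWHM 2.5 h, 10-min sampling
  t_h <- (0:96) * 10 / 60
  sdh <- 2.5 / (2 * sqrt(2 * log(2)))
  y <- 1 + 0.5 * exp(-(t_h - 8)^2 / (2 * sdh^2))
  res <- detect_pulses(y, pk, 10)
  expect_equal(nrow(res), 1)
  expect_equal(res$amplitude, 1.5, tolerance = 0.01)
  expect_equal(res$duration_h, 2.5, tolerance = 10 / 60) # within one sample
  # sub-threshold fold 1.25 yields nothing
  y2 <- 1 + 0.25 * exp(-(t_h - 8)^2 / (2 * sdh^2))
  expect_equal(nrow(detect_pulses(y2, pk, 10)), 0)
  expect_error(detect_pulses(numeric(1), peak_params(smooth_window = 2), 10),
               "shorter")
})

test_that("raising height or prominence never increases the peak count", {
  set.seed(42)
  for (i in 1:10) {
    y <- 1 + abs(cumsum(rnorm(120, 0, 0.05)))
    y <- y / min(y)
    base <- nrow(detect_pulses(y, peak_params(), 10))
    for (h in c(1.4, 1.6, 2)) {
      expect_lte(nrow(detect_pulses(y, peak_params(height = h), 10)), base)
    }
    for (pr in c(0.35, 0.5, 1)) {
      expect_lte(nrow(detect_pulses(y, peak_params(prominence = pr), 10)), base)
    }
  }
})

test_that("pulse calls are invariant to per-cell gain", {
  # exact invariance of the per-trace stage: min-normalization removes gain
  t_h <- (0:80) * 10 / 60
  sdh <- 2.5 / (2 * sqrt(2 * log(2)))
  set.seed(5)
  y <- 100 * (1 + 0.5 * exp(-(t_h - 6)^2 / (2 * sdh^2))) * exp(rnorm(81, 0, 0.03))
  a <- detect_pulses(y / min(y), peak_params(), 10)
  b <- detect_pulses((y * 7.3) / min(y * 7.3), peak_params(), 10)
  expect_equal(a, b, tolerance = 1e-12)

  # in a large cohort, rescaling one cell leaves every cell's call set
  # unchanged (the per-frame cohort mean shifts only by ~1/N)
  p <- yap_pulse_params(pulse_rate = 1, noise_cv = 0.03)
  raw <- simulate_yap_cohort(p, 50, 14, seed = 5)$traces
  scaled <- raw |>
    dplyr::mutate(yap_au = ifelse(cell_id == "cell_007", yap_au * 3, yap_au),
                  mcp_au = ifelse(cell_id == "cell_007", mcp_au * 3, mcp_au))
  r1 <- detect_yap_pulses(raw, dt_min = 10)
  r2 <- detect_yap_pulses(scaled, dt_min = 10)
  c1 <- table(factor(r1$calls$cell_id, levels = unique(raw$cell_id)))
  c2 <- table(factor(r2$calls$cell_id, levels = unique(raw$cell_id)))
  expect_identical(c1, c2)
  expect_equal(r1$calls$peak_time_h, r2$calls$peak_time_h)
})

test_that("pulse count recovery on well-separated pulses", {
  p <- yap_pulse_params(pulse_rate = 1.2, noise_cv = 0.03, amp_sd = 0)
  co <- simulate_yap_cohort(p, 80, 16, seed = 11)
  res <- detect_yap_pulses(co$traces, dt_min = 10)
  passing <- res$qc$cell_id[res$qc$qc_status == "pass"]
  gt <- co$ground_truth$pulses
  # restrict to cells whose true pulses are interior to the analyzed window
  # and mutually separated (overlapping bumps merge into one maximum by
  # construction, which is not a detector failure)
  ok_cell <- vapply(passing, function(cid) {
    ctr <- sort(gt$pulse_center_h[gt$cell_id == cid])
    all(ctr > 1.5 & ctr < 14.5) && (length(ctr) < 2 || min(diff(ctr)) > 3)
  }, logical(1))
  cells <- passing[ok_cell]
  truth <- table(factor(gt$cell_id[gt$cell_id %in% cells], levels = cells))
  found <- table(factor(res$calls$cell_id, levels = cells))
  expect_gte(length(cells), 30)
  expect_gte(mean(truth == found), 0.95)
})

test_that("cohort summary and false-positive rate book-keeping", {
  calls <- tibble::tibble(cell_id = c("a", "a", "b", "c"),
                          duration_h = rep(2.5, 4),
                          amplitude = c(1.5, 1.6, 1.4, 1.5))
  cells <- sprintf("%s", letters[1:10])
  s <- summarize_pulsing(calls, cells)
  expect_equal(s$fraction_pulsing, 0.3)
  expect_equal(s$duration_h$mean, 2.5)
  expect_equal(s$duration_h$median, 2.5)
  expect_equal(false_positive_rate(calls[calls$cell_id == "a", ],
                                   letters[1:50]), 0.02)
  expect_error(summarize_pulsing(calls, character()), "cells")

  # noiseless constant controls yield zero false positives
  co <- flat_cohort(10, 97)
  r <- detect_yap_pulses(co, dt_min = 10)
  pass <- r$qc$cell_id[r$qc$qc_status == "pass"]
  expect_equal(false_positive_rate(r$calls, pass), 0)
})

test_that("detected amplitudes track the true fold at low noise", {
  p <- yap_pulse_params(pulse_rate = 1, noise_cv = 0.01)
  co <- simulate_yap_cohort(p, 100, 16, seed = 21)
  res <- detect_yap_pulses(co$traces, dt_min = 10)
  pass <- res$qc$cell_id[res$qc$qc_status == "pass"]
  s <- summarize_pulsing(res$calls, pass)
  expect_lt(abs(s$amplitude$mean - 1.5), 0.1)
  expect_lt(abs(s$duration_h$mean - 2.5), 0.35)
})
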