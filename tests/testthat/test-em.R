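# EM and bootstrap tests use small windows (w = 3, dt = 90 s) so the
# compound space stays at 8 states and each fit takes well under a second.

sim_cohort <- function(k_on_h, k_off_h = 2, r = 2, w = 3, dt = 90,
                       sigma = 1.5, n_cells = 30, n_steps = 150, seed = 1) {
  pp <- promoter_params(k_on = k_on_h / 60, k_off = k_off_h / 60, r = r,
                        w = w, dt = dt, sigma_noise = sigma)
  trace_list(simulate_trace_cohort(pp, n_cells, n_steps, seed = seed)$traces)
}

test_that("EM log-likelihood is monotone non-decreasing", {
  tr <- sim_cohort(0.8, seed = 3, n_cells = 10, n_steps = 120)
  fit <- em_fit(tr, w = 3, dt = 90, n_starts = 2, seed = 2)
  d <- diff(fit$loglik_path)
  expect_true(all(d >= -1e-9 * abs(fit$loglik_path[-1])))
})

test_that("EM recovers burst parameters within 20% on an in-model cohort", {
  tr <- sim_cohort(0.6, k_off_h = 2, n_cells = 40, n_steps = 300, seed = 4)
  fit <- em_fit(tr, w = 3, dt = 90, n_starts = 3, seed = 5)
  expect_lt(abs(fit$k_on - 0.01) / 0.01, 0.2)
  expect_lt(abs(fit$k_off - 2 / 60) / (2 / 60), 0.2)
  expect_lt(abs(fit$amplitude - 2) / 2, 0.2)
})

test_that("all-OFF data is flagged degenerate with k_on at the boundary", {
  set.seed(6)
  tr <- purrr::map(1:5, ~ rnorm(200, 0, 0.5))
  fit <- em_fit(tr, w = 3, dt = 90, n_starts = 2, seed = 7)
  expect_true(fit$degenerate)
})

test_that("a 4x difference in k_on is recovered as a ~4x frequency fold", {
  a <- em_fit(sim_cohort(0.5, n_cells = 40, n_steps = 250, seed = 8),
              w = 3, dt = 90, n_starts = 3, seed = 9)
  b <- em_fit(sim_cohort(2.0, n_cells = 40, n_steps = 250, seed = 10),
              w = 3, dt = 90, n_starts = 3, seed = 11)
  expect_lt(abs(b$frequency / a$frequency - 4) / 4, 0.25)
})

test_that("frequency is monotone in k_on; duration and amplitude are specific", {
  k_ons <- c(0.4, 1.2, 4) # a 10x span
  fits <- purrr::map(seq_along(k_ons), function(i) {
    em_fit(sim_cohort(k_ons[i], n_cells = 35, n_steps = 250, seed = 20 + i),
           w = 3, dt = 90, n_starts = 3, seed = 30 + i)
  })
  freqs <- purrr::map_dbl(fits, "frequency")
  expect_true(all(diff(freqs) > 0))
  for (i in seq_along(fits)) {
    expect_lt(abs(fits[[i]]$frequency - k_ons[i] / 60) / (k_ons[i] / 60), 0.25)
    expect_lt(abs(fits[[i]]$duration - 30) / 30, 0.25)   # 1/k_off = 30 min
    expect_lt(abs(fits[[i]]$amplitude - 2) / 2, 0.25)
  }
})

test_that("scaled-MAD outlier removal matches hand computation", {
  res <- remove_outliers(c(1, 1.1, 0.9, 1.05, 100))
  expect_equal(sort(res$kept), c(0.9, 1, 1.05, 1.1))
  expect_identical(remove_outliers(rep(2, 5))$kept, rep(2, 5))
  expect_warning(kept0 <- remove_outliers(c(1, 1, 1, 5))$kept, "median")
  expect_identical(kept0, c(1, 1, 1))
  expect_error(remove_outliers(c(1, 2)), "3 values")
  # ~3 SD rule: about 0.27% of a Gaussian sample is removed in expectation
  set.seed(12)
  x <- rnorm(1000)
  expect_lte(1 - length(remove_outliers(x)$kept) / 1000, 0.01)
})

test_that("bootstrap floors are enforced and summaries are sane", {
  tr <- sim_cohort(1.5, n_cells = 12, n_steps = 120, seed = 40)
  expect_error(bootstrap_inference(tr, 3, 90, n_boot = 15), ">= 16")
  expect_error(bootstrap_inference(tr, 3, 90, min_timepoints = 999), ">= 1000")
  bs <- bootstrap_inference(tr, w = 3, dt = 90, n_boot = 16, n_starts = 2,
                            seed = 41)
  # a rare replicate may land on a degenerate optimum and be dropped
  expect_gte(nrow(bs$replicates), 14)
  expect_true(all(lengths(bs$kept) <= 16))
  expect_lt(abs(bs$mean[["frequency"]] - 1.5 / 60),
            max(2 * bs$sd[["frequency"]], 0.3 * 1.5 / 60))
  expect_true(all(bs$sd >= 0))
})

test_that("a single-cell cohort collapses replicate variation", {
  tr <- sim_cohort(1.5, n_cells = 1, n_steps = 1100, seed = 50)
  bs <- bootstrap_inference(tr, w = 3, dt = 90, n_boot = 16, n_starts = 2,
                            seed = 51)
  # identical data in every replicate: spread only from EM start jitter
  expect_lt(bs$sd[["frequency"]] / bs$mean[["frequency"]], 1e-3)
})
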