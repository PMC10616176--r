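test_that("absorbing limits of the telegraph chain", {
  off <- promoter_params(k_on = 0, k_off = 0.1, r = 5, w = 3, dt = 30)
  expect_true(all(simulate_promoter_path(off, 500, seed = 1) == 0))
  on <- promoter_params(k_on = 0.1, k_off = 0, r = 5, w = 3, dt = 30)
  s <- simulate_promoter_path(on, 500, seed = 2, init = "on")
  expect_true(all(s == 1))
  # k_off = 0: once ON, stays ON
  s2 <- simulate_promoter_path(on, 2000, seed = 3, init = "off")
  first_on <- which(s2 == 1)[1]
  expect_true(all(s2[first_on:length(s2)] == 1))
})

test_that("stationary occupancy matches k_on / (k_on + k_off) within 3 SE", {
  pp <- promoter_params(k_on = 0.05, k_off = 0.05, r = 10, w = 3, dt = 30)
  n <- 1e5
  s <- simulate_promoter_path(pp, n, seed = 7)
  A <- promoter_step_matrix(0.05, 0.05, 30)
  # autocorrelated binary chain: var of the mean inflated by (1+phi)/(1-phi)
  phi <- 1 - A[1, 2] - A[2, 1]
  se <- sqrt(0.25 * (1 + phi) / (1 - phi) / n)
  expect_lt(abs(mean(s) - 0.5), 3 * se)
})

test_that("MS2 rendering: plateau, ramp, boxcar and bounds", {
  pp <- promoter_params(1, 1, r = 2, w = 4, dt = 30) # load/step = 1
  f_on <- render_ms2_trace(rep(1, 12), pp)
  expect_equal(f_on[1:4], 1:4)            # linear ramp over first w steps
  expect_equal(f_on[4:12], rep(4, 9))     # then plateau at calib*r*dt*w
  expect_equal(render_ms2_trace(rep(0, 12), pp), rep(0, 12))
  st <- rep(0, 10); st[4] <- 1
  pp3 <- promoter_params(1, 1, r = 2, w = 3, dt = 30)
  expect_equal(render_ms2_trace(st, pp3), c(0, 0, 0, 1, 1, 1, 0, 0, 0, 0))
  expect_error(render_ms2_trace(rep(1, 2), pp3), "exceeds")
})

test_that("noiseless signal is bounded in [0, saturation] for random paths", {
  pp <- promoter_params(0.03, 0.06, r = 3, w = 6, dt = 30)
  sat <- ms2_saturation(pp)
  for (seed in 1:10) {
    s <- simulate_promoter_path(pp, 400, seed = seed)
    f <- render_ms2_trace(s, pp)
    expect_true(all(f >= 0 & f <= sat + 1e-12))
  }
})

test_that("cohort simulation is deterministic and correctly sized", {
  pp <- promoter_params(0.02, 0.04, r = 2, w = 4, dt = 30, sigma_noise = 0.5)
  a <- simulate_trace_cohort(pp, 10, 100, seed = 1)
  b <- simulate_trace_cohort(pp, 10, 100, seed = 1)
  expect_identical(a, b)
  expect_equal(nrow(a$traces), 10 * 100)
  c2 <- simulate_trace_cohort(pp, 10, 100, seed = 2)
  expect_false(identical(a$traces$ms2_au, c2$traces$ms2_au))
})

test_that("cohort mean approaches the stationary convolved level", {
  pp <- promoter_params(0.05, 0.05, r = 2, w = 4, dt = 30) # noiseless
  co <- simulate_trace_cohort(pp, 60, 400, seed = 9)
  cell_means <- tapply(co$traces$ms2_au, co$traces$cell_id, mean)
  expected <- ms2_saturation(pp) * 0.05 / (0.05 + 0.05)
  se <- sd(cell_means) / sqrt(length(cell_means))
  expect_lt(abs(mean(cell_means) - expected), 3 * se)
})

test_that("ramp emission option spreads a polymerase's contribution", {
  pp <- promoter_params(1, 1, r = 2, w = 4, dt = 30)
  st <- rep(0, 10); st[3] <- 1
  f <- render_ms2_trace(st, pp, ramp = TRUE)
  expect_equal(f[3:6], c(1, 2, 3, 4) / 4) # builds to full over w steps
})

test_that("parameter validation rejects invalid inputs", {
  expect_error(promoter_params(-1, 1, 1, 3, 30), ">= 0")
  expect_error(promoter_params(1, 1, 1, 0, 30), "integer")
  expect_error(promoter_params(NaN, 1, 1, 3, 30), "finite")
  expect_error(promoter_params(1, 1, 1, 3, 0), "dt")
})
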