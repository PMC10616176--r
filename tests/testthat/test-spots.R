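make_scene <- function(spots, noise = 10, mcp = 100, shape = c(15, 64, 64)) {
  simulate_spot_stack(spot_scene(shape, spots, mcp_level = mcp,
                                 noise_sd = noise), seed = 99)
}

two_spots <- tibble::tibble(
  x0 = c(20.3, 45.7), y0 = c(30.6, 22.2), z0 = c(7.4, 8.6),
  amplitude = c(400, 300), sigma_xy = c(1.3, 1.5), sigma_z = c(2, 2))

test_that("candidate detection: uniform, single and double spots", {
  flat <- simulate_spot_stack(spot_scene(c(5, 32, 32), mcp_level = 100))
  expect_equal(nrow(detect_candidates(flat$stack)), 0)
  expect_error(detect_candidates(array(0, c(0, 4, 4))), "empty")

  one <- make_scene(two_spots[1, ])
  cand <- detect_candidates(one$stack)
  expect_equal(nrow(cand), 1)
  expect_lte(abs(cand$y - 30.6), 1)
  expect_lte(abs(cand$x - 20.3), 1)

  pair <- tibble::tibble(x0 = c(25, 35), y0 = c(30, 30), z0 = c(8, 8),
                         amplitude = c(350, 350), sigma_xy = 1.4, sigma_z = 2)
  both <- make_scene(pair)
  expect_equal(nrow(detect_candidates(both$stack)), 2)
})

test_that("noiseless spot fits recover center and widths", {
  st <- make_scene(two_spots[1, ], noise = 0)
  cand <- detect_candidates(st$stack, threshold = 1)
  fit <- fit_spot(st$stack, cand[1, ])
  expect_true(fit$accepted)
  expect_lt(abs(fit$x0 - 20.3), 0.1)
  expect_lt(abs(fit$y0 - 30.6), 0.1)
  expect_lt(abs(fit$sigma_x - 1.3) / 1.3, 0.05)
  expect_lt(abs(fit$sigma_y - 1.3) / 1.3, 0.05)
  expect_lt(abs(fit$z0 - 7.4), 0.2)
})

test_that("flat-background candidates and boundary spots are rejected", {
  flat <- make_scene(NULL, noise = 5)
  fit <- fit_spot(flat$stack, tibble::tibble(y = 30, x = 30))
  expect_false(fit$accepted)
  edge <- make_scene(tibble::tibble(x0 = 30, y0 = 30, z0 = 1, amplitude = 400,
                                    sigma_xy = 1.4, sigma_z = 1.5), noise = 0)
  fe <- fit_spot(edge$stack, tibble::tibble(y = 30, x = 30))
  expect_false(fe$accepted)
  expect_equal(fe$reason, "z_boundary")
})

test_that("localization RMSE stays below 0.2 px at SNR ~ 10", {
  errs <- c()
  for (i in 1:6) {
    x0 <- 15 + i * 5 + 0.37; y0 <- 40 - i * 3 + 0.21
    st <- simulate_spot_stack(
      spot_scene(c(15, 64, 64),
                 tibble::tibble(x0 = x0, y0 = y0, z0 = 8, amplitude = 400,
                                sigma_xy = 1.4, sigma_z = 2),
                 mcp_level = 100, noise_sd = 40), seed = 100 + i)
    cand <- detect_candidates(st$stack)
    expect_gte(nrow(cand), 1)
    fit <- fit_spot(st$stack, cand[which.max(cand$response), ])
    errs <- c(errs, (fit$x0 - x0)^2 + (fit$y0 - y0)^2)
  }
  expect_lt(sqrt(mean(errs)), 0.2 * sqrt(2))
})

test_that("integration matches a numeric Gaussian-region oracle within 2%", {
  # sigma small enough that the background annulus sees no spot tails
  sp <- tibble::tibble(x0 = 32, y0 = 32, z0 = 8, amplitude = 500,
                       sigma_xy = 1.2, sigma_z = 2)
  st <- make_scene(sp, noise = 0)
  fit <- fit_spot(st$stack, tibble::tibble(y = 32, x = 32))
  got <- integrate_spot(st$stack, fit)
  oracle <- gaussian_region_sum(c(15, 64, 64), 32, 32, 8, 500, 1.2, 2,
                                r_xy = 2 * max(fit$sigma_x, fit$sigma_y))
  expect_lt(abs(got - oracle) / oracle, 0.02)
  # flat background integrates to zero
  flat <- make_scene(NULL, noise = 0)
  fit_flat <- fit
  expect_equal(integrate_spot(flat$stack, fit_flat), 0)
})

test_that("integration is invariant to background level and offsets", {
  sp <- tibble::tibble(x0 = 30, y0 = 34, z0 = 8, amplitude = 500,
                       sigma_xy = 1.2, sigma_z = 2)
  st1 <- make_scene(sp, noise = 0, mcp = 100)
  st2 <- make_scene(sp, noise = 0, mcp = 200)
  fit <- fit_spot(st1$stack, tibble::tibble(y = 34, x = 30))
  s1 <- integrate_spot(st1$stack, fit)
  s2 <- integrate_spot(st2$stack, fit)
  s3 <- integrate_spot(st1$stack + 57.3, fit)
  expect_equal(s1, s2, tolerance = 1e-6)
  expect_equal(s1, s3, tolerance = 1e-6)
})

test_that("MCP correction: identity, exact quadratic, band exclusion", {
  same <- tibble::tibble(mcp_au = rep(120, 8),
                         mean_spot_intensity = rnorm(8, 50, 1))
  corr <- build_mcp_correction(same)
  expect_equal(corr$correct(c(10, 20), c(120, 120)), c(10, 20))

  m <- seq(55, 195, length.out = 12)
  quad <- tibble::tibble(mcp_au = m,
                         mean_spot_intensity = 2 + 0.1 * m + 0.001 * m^2)
  c2 <- build_mcp_correction(quad)
  raw <- 2 + 0.1 * m + 0.001 * m^2
  corrected <- c2$correct(raw, m)
  expect_lt(diff(range(corrected)) / mean(corrected), 1e-6)
  expect_true(is.na(c2$correct(10, 30))) # below the valid band
  expect_error(build_mcp_correction(quad[1:4, ]), ">= 6")
})

test_that("correction removes the MCP dependence of spot intensities", {
  set.seed(31)
  m <- runif(40, 55, 195)
  true_int <- 100
  observed <- true_int * (0.4 + 0.004 * m) * (1 + rnorm(40, 0, 0.02))
  corr <- build_mcp_correction(
    tibble::tibble(mcp_au = m, mean_spot_intensity = observed))
  fixed <- corr$correct(observed, m)
  refit <- lm(fixed ~ m)
  slope_t <- summary(refit)$coefficients["m", "t value"]
  expect_lt(abs(slope_t), 2)
})

test_that("trace assembly: summation, zero-filling, blinking", {
  rows <- tibble::tibble(
    nucleus_id = c("n1", "n1", "n2"),
    frame = c(0L, 0L, 2L),
    sum_intensity = c(100, 50, 70),
    mcp_au = 120)
  tr <- assemble_ms2_traces(rows, frames = 0:3)
  expect_equal(tr$ms2_au[tr$cell_id == "n1" & tr$frame == 0], 150)
  expect_equal(tr$ms2_au[tr$cell_id == "n1" & tr$frame == 2], 0)
  expect_equal(tr$ms2_au[tr$cell_id == "n2" & tr$frame == 2], 70)
  expect_equal(sum(tr$ms2_au > 0), 2)
  validate_trace_table(tr)
  expect_error(validate_trace_table(dplyr::bind_rows(tr, tr[1, ])),
               "duplicate")
})
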