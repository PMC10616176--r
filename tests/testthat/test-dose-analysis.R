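make_pop <- function(seed, n = 1200, condition = "dark", replicate = 1,
                     oct4 = hill_curve(1, 0.05, 100, 1.6)) {
  simulate_dose_population(
    dose_pop_params(n_cells = n, oct4_curve = oct4),
    seed = seed, condition = condition, replicate = replicate)$cells
}

test_that("replicate scaling: single-replicate identity and gain cancellation", {
  d1 <- make_pop(1)
  s1 <- scale_replicates(d1)
  # one replicate: mid / grand-mean factor is 1, doses unchanged
  expect_equal(sort(s1$cells$yap_au), sort(d1$yap_au[d1$yap_au > 0]))
  # two replicates identical up to a 2x dose gain coincide after scaling
  d2 <- d1
  d2$replicate <- 2L
  d2$yap_au <- d2$yap_au * 2
  s2 <- scale_replicates(dplyr::bind_rows(d1, d2))
  a <- sort(s2$cells$yap_au[s2$cells$replicate == 1])
  b <- sort(s2$cells$yap_au[s2$cells$replicate == 2])
  expect_equal(a, b, tolerance = 1e-3)
  # normalized responses lie in [0, 1] up to noise overshoot
  expect_gt(mean(s2$cells$oct4_au > -0.25 & s2$cells$oct4_au < 1.25), 0.99)
})

test_that("replicate scaling is idempotent", {
  d <- dplyr::bind_rows(make_pop(2), {
    x <- make_pop(3, replicate = 2)
    x$yap_au <- x$yap_au * 1.5
    x
  })
  once <- scale_replicates(d)
  twice <- scale_replicates(once$cells)
  expect_equal(sort(twice$cells$yap_au), sort(once$cells$yap_au),
               tolerance = 0.05)
})

test_that("gating and delta against the dark control", {
  dark <- make_pop(4, condition = "dark")
  fit <- fit_hill(dark$yap_au, dark$oct4_au)
  same <- dark
  same$condition <- "lit"
  both <- dplyr::bind_rows(dark, same)
  g <- gate_and_delta(both, fit, q = 50, effect_column = "oct4_au")
  expect_equal(g$delta[g$condition == "lit"], 0)
  # raising the gated population's Oct4 by 25% of the low-expressor level
  low_ref <- median(dark$oct4_au[dark$yap_au < icq(fit, 5)])
  up <- dark
  up$condition <- "pulsed"
  up$oct4_au <- up$oct4_au + 0.25 * low_ref
  g2 <- gate_and_delta(dplyr::bind_rows(dark, up), fit, q = 50,
                       effect_column = "oct4_au")
  expect_equal(g2$delta[g2$condition == "pulsed"], 0.25, tolerance = 1e-6)
  # an IC5 gate admits at least as many cells as an IC50 gate
  g5 <- gate_and_delta(both, fit, q = 5, effect_column = "oct4_au")
  expect_gte(g5$n_gated[1], g$n_gated[1])
})

test_that("lineage classification recovers well-separated ground truth", {
  cells <- make_pop(5, n = 3000)
  rules <- list(
    meso = cutoff_rule("tbra_au", "sox1_au"),
    endo = cutoff_rule("foxa2_au", "sox1_au"),
    ecto = cutoff_rule("sox1_au", "tbra_au")
  )
  cl <- classify_lineage(cells, rules)
  for (lin in names(rules)) {
    truth <- cells$lineage_true == lin
    called <- cl$cells[[paste0(lin, "_pos")]]
    acc <- mean(truth == called)
    expect_gte(acc, 0.95)
  }
  # monotonicity: inflating the opposing-gate SD raises cutoffs
  noisy <- cells
  gate <- noisy$sox1_au >= quantile(noisy$sox1_au, 0.9)
  noisy$tbra_au[gate] <- noisy$tbra_au[gate] *
    exp(rnorm(sum(gate), 0, 0.8))
  cl2 <- classify_lineage(noisy, rules["meso"])
  expect_gt(cl2$cutoffs[["meso"]], cl$cutoffs[["meso"]])

  # all-background population yields ~zero positive fractions
  bg <- cells
  for (m in c("sox1_au", "tbra_au", "foxa2_au")) {
    bg[[m]] <- pmax(rnorm(nrow(bg), 100, 20), 1)
  }
  cl3 <- classify_lineage(bg, rules)
  expect_true(all(cl3$fractions < 0.05))
})

test_that("dose binning normalizes to the lowest bin and conserves counts", {
  cells <- make_pop(6)
  flat <- cells
  flat$otx2_au <- 100
  b <- bin_and_summarize(flat, "yap_au", "otx2_au", bins = 5)
  expect_true(all(abs(b$mean_value - 1) < 1e-12))
  expect_equal(sum(b$n), nrow(flat))
  floor_val <- median(cells$yap_au)
  b2 <- bin_and_summarize(cells, "yap_au", "otx2_au", bins = 4,
                          dose_floor = floor_val)
  expect_equal(sum(b2$n), sum(cells$yap_au >= floor_val))
  # monotone repression: binned means non-increasing in dose
  b3 <- bin_and_summarize(cells, "yap_au", "oct4_au", bins = 5)
  expect_true(all(diff(b3$mean_value) < 0.05))
  expect_error(bin_and_summarize(cells, "yap_au", "oct4_au",
                                 bins = c(0, 1e9)), "2 bins")
})
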