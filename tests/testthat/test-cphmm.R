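test_that("forward-backward equals exhaustive path enumeration (T <= 6, w <= 2)", {
  cases <- expand.grid(k_on = c(0.5, 1.2), k_off = c(0.5, 2.5), w = 1:2)
  set.seed(13)
  for (i in seq_len(nrow(cases))) {
    m <- build_compound_model(cases$k_on[i], cases$k_off[i], r = 8,
                              sigma = 1.1, w = cases$w[i], dt = 30, b = 0.3)
    for (T_ in c(3, 5, 6)) {
      f <- rnorm(T_, 2, 2)
      fb <- forward_backward(f, m)
      expect_lt(abs(fb$loglik - brute_force_loglik(f, m)), 1e-8)
      expect_true(all(abs(rowSums(fb$posterior) - 1) < 1e-10))
    }
  }
})

test_that("w = 1 reduces to the ordinary two-state HMM", {
  m <- build_compound_model(1, 2, r = 6, sigma = 1, w = 1, dt = 30)
  expect_equal(length(m$init), 2)
  set.seed(5)
  f <- rnorm(6, 1, 1.5)
  expect_lt(abs(forward_backward(f, m)$loglik - brute_force_loglik(f, m)),
            1e-8)
})

test_that("symmetric rates give a symmetric step matrix and uniform stationary", {
  m <- build_compound_model(0.8, 0.8, r = 5, sigma = 1, w = 2, dt = 30)
  expect_equal(m$A[1, 2], m$A[2, 1])
  expect_equal(sum(m$init), 1)
  # promoter marginal of the initial register distribution is uniform
  cur_on <- bitwAnd(0:3, 1L) == 1L
  expect_equal(sum(m$init[cur_on]), 0.5)
})

test_that("rates round-trip through the step matrix within 1e-10", {
  for (k_on in c(0.01, 0.3, 2)) {
    for (k_off in c(0.05, 1.5)) {
      for (dt in c(30, 90)) {
        A <- promoter_step_matrix(k_on, k_off, dt)
        r <- rates_from_step_matrix(A, dt)
        expect_lt(abs(r$k_on - k_on), 1e-10)
        expect_lt(abs(r$k_off - k_off), 1e-10)
      }
    }
  }
  expect_error(rates_from_step_matrix(matrix(c(0.1, 0.8, 0.9, 0.2), 2), 30),
               "embeddable")
})

test_that("flat emissions push posteriors to the prior marginals", {
  m <- build_compound_model(1, 2, r = 6, sigma = 500, w = 2, dt = 30)
  f <- c(1, 4, 2, 6, 3)
  fb <- forward_backward(f, m)
  pi_on <- 1 / 3 # k_on / (k_on + k_off)
  expect_true(all(abs(fb$p_on - pi_on) < 0.01))
})

test_that("impossible traces return -Inf log-likelihood flagged, not an error", {
  m <- build_compound_model(1, 2, r = 6, sigma = 1e-3, w = 2, dt = 30)
  fb <- forward_backward(rep(1e6, 5), m)
  expect_false(fb$ok)
  expect_identical(fb$loglik, -Inf)
})

test_that("the compound state space is capped", {
  expect_error(build_compound_model(1, 1, 1, 1, w = 13, dt = 30),
               "cap")
  expect_silent(build_compound_model(1, 1, 1, 1, w = 13, dt = 30,
                                     state_cap = 2^13))
})
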