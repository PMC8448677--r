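test_that("initial-rate fit recovers exact lines and flat traces", {
  tt <- 0:20
  tr <- progress_trace(tt, 3 + 5 * tt)
  est <- fit_initial_rate(tr, window = c(0, 20))
  expect_equal(est$rate, 5, tolerance = 1e-12)
  expect_equal(est$intercept, 3, tolerance = 1e-12)
  expect_equal(est$r_squared, 1)
  expect_true(est$qc_pass)

  flat <- fit_initial_rate(progress_trace(tt, rep(7, 21)), window = c(0, 20))
  expect_equal(flat$rate, 0)
  expect_equal(flat$r_squared, 1)   # a constant is fit perfectly by its mean
})

test_that("slope estimator is scale-equivariant", {
  set.seed(5)
  tt <- 0:30
  sig <- 2 + 0.7 * tt + rnorm(31, 0, 0.3)
  r1 <- fit_initial_rate(progress_trace(tt, sig), window = c(0, 30))$rate
  r2 <- fit_initial_rate(progress_trace(tt, 10 * sig), window = c(0, 30))$rate
  expect_equal(r2, 10 * r1, tolerance = 1e-12)
})

test_that("hydrolysed-fraction QC has deterministic boundary behaviour", {
  tt <- seq(0, 60, by = 2)
  # calibration: 1e9 signal units per M of product, 20 uM substrate
  mk <- function(total_delta) progress_trace(
    tt, total_delta * tt / 60, substrate_conc = 2e-5, signal_per_product = 1e9)
  at_bound <- mk(2000)
  expect_equal(hydrolysis_fraction(at_bound), 0.10)
  expect_true(fit_initial_rate(at_bound, window = c(0, 60))$qc_pass)
  over <- mk(4000)
  expect_equal(hydrolysis_fraction(over), 0.20)
  expect_false(fit_initial_rate(over, window = c(0, 60))$qc_pass)
  # zero signal change hydrolyses nothing
  none <- progress_trace(tt, rep(1, length(tt)), substrate_conc = 2e-5,
                         signal_per_product = 1e9)
  expect_equal(hydrolysis_fraction(none), 0)
})

test_that("missing calibration leaves hydrolysis unknown without failing QC", {
  tt <- 0:20
  tr <- progress_trace(tt, 5 * tt, substrate_conc = 2e-5)
  expect_message(hf <- hydrolysis_fraction(tr), "unknown")
  expect_true(is.na(hf))
  est <- suppressMessages(fit_initial_rate(tr, window = c(0, 20)))
  expect_true(is.na(est$hydrolysis_fraction))
  expect_true(est$qc_pass)
  expect_error(hydrolysis_fraction(progress_trace(tt, 5 * tt)),
               "substrate_conc")
})

test_that("nonlinear windows fail the linearity QC", {
  tt <- 0:60
  curved <- progress_trace(tt, 100 * (1 - exp(-tt / 15)))   # strong curvature
  est <- fit_initial_rate(curved, window = c(0, 60))
  expect_false(est$qc_pass)
  expect_lt(est$r_squared, 0.98)
})

test_that("blank traces are subtracted pointwise before fitting", {
  tt <- 0:20
  tr <- progress_trace(tt, 10 + 5 * tt + 0.5 * tt)   # enzyme + drifting blank
  bl <- progress_trace(tt, 10 + 0.5 * tt)
  est <- fit_initial_rate(tr, window = c(0, 20), blank = bl)
  expect_equal(est$rate, 5, tolerance = 1e-12)
  expect_equal(est$intercept, 0, tolerance = 1e-10)
  expect_error(fit_initial_rate(tr, window = c(0, 20),
                                blank = progress_trace(tt + 1, tt)),
               "same times")
})

test_that("degenerate windows and traces are rejected", {
  tt <- 0:20
  tr <- progress_trace(tt, 5 * tt)
  expect_error(fit_initial_rate(tr, window = c(0, 2)), ">= 4")
  expect_error(progress_trace(c(0, 1, 2), c(0, 1, 2)), ">= 4")
  expect_error(progress_trace(c(0, 1, 1, 2), 1:4), "strictly increasing")
  expect_error(progress_trace(tt, c(rep(1, 20), NA)), "finite")
})
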