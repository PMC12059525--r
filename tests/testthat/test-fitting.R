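test_that("noiseless samples recover the generating biexponential exactly", {
  p <- par_tumor()
  truth <- biexp_default()
  fit <- fit_biexponential(truth_samples(truth), p)
  expect_true(fit$converged)
  expect_equal(fit$n_points, 4L)
  expect_lt(fit$residual_norm, 1e-8)
  expect_equal(fit$model$r0, truth$r0, tolerance = 1e-6)
  expect_equal(fit$model$lambda_e1, truth$lambda_e1, tolerance = 1e-6)
  expect_equal(fit$model$lambda_e2, truth$lambda_e2, tolerance = 1e-6)
  # round trip: dose and EQD2 recovered
  expect_equal(total_dose(fit$model), total_dose(truth), tolerance = 1e-6)
  expect_equal(compute_eqdx(fit$model, p, engine = "analytic")$EQDX,
               compute_eqdx(truth, p, engine = "analytic")$EQDX,
               tolerance = 1e-6)
  # the same holds across other truths (round-trip property)
  for (m in list(biexp_dose_rate(0.6, 0.008, 0.9),
                 biexp_dose_rate(5, 0.04, 0.12))) {
    f <- fit_biexponential(truth_samples(m, c(1, 4, 24, 72, 120)), p)
    expect_equal(f$model$lambda_e1, m$lambda_e1, tolerance = 1e-6)
    expect_equal(f$model$lambda_e2, m$lambda_e2, tolerance = 1e-6)
  }
})

test_that("underdetermined fits are rejected", {
  p <- par_tumor()
  expect_error(fit_biexponential(dose_rate_samples(c(1, 24), c(1, 0.4)), p),
               "3 samples")
})

test_that("fitting is deterministic across repeated calls", {
  p <- par_tumor()
  s <- dose_rate_samples(c(1, 4, 24, 72), c(0.71, 1.52, 1.19, 0.52))
  f1 <- fit_biexponential(s, p)
  f2 <- fit_biexponential(s, p)
  expect_identical(stats::setNames(unlist(f1$model), NULL),
                   stats::setNames(unlist(f2$model), NULL))
})

test_that("tail decay constant comes from the final log-slope", {
  p <- par_tumor()
  s <- dose_rate_samples(c(1, 4, 24, 72), c(1, 0.8, 0.4, 0.2))
  expect_equal(estimate_tail_lambda(s, 2L, p), log(2) / 48)
  # three-point variant: exact for points on one exponential
  s3 <- dose_rate_samples(c(4, 24, 72), 2 * exp(-0.03 * c(4, 24, 72)))
  expect_equal(estimate_tail_lambda(s3, 3L, p), 0.03, tolerance = 1e-12)
})

test_that("non-decaying tails fall back to physical decay only", {
  p <- par_tumor()
  lam <- p$phys_lambda
  # final sample larger than the preceding one
  s_up <- dose_rate_samples(c(1, 4, 24, 72), c(0.1, 0.3, 0.4, 0.41))
  expect_equal(estimate_tail_lambda(s_up, 2L, p), lam)
  # equal final samples: zero biological clearance
  s_eq <- dose_rate_samples(c(1, 4, 24, 72), c(0.1, 0.3, 0.5, 0.5))
  expect_equal(estimate_tail_lambda(s_eq, 2L, p), lam)
  # decaying, but slower than physical decay alone: still floored
  s_slow <- dose_rate_samples(c(24, 72), c(0.5, 0.5 * exp(-lam * 48 / 2)))
  expect_equal(estimate_tail_lambda(s_slow, 2L, p), lam)
  # zero dose rate in the tail is rejected (log undefined)
  expect_error(estimate_tail_lambda(
    dose_rate_samples(c(24, 72), c(0.4, 0)), 2L, p), "positive")
})

test_that("piecewise assembly anchors the tail at the right sample", {
  p <- par_tumor()
  s <- dose_rate_samples(c(1, 4, 24, 72), c(1, 0.8, 0.4, 0.2))
  pw <- build_piecewise(s, 2L, p)
  expect_equal(pw$tx, 24)  # second-to-last sample
  expect_equal(pw$lambda_e, log(2) / 48)
  # the analytic tail passes through the omitted final sample exactly
  expect_equal(dose_rate(pw, 72), 0.2, tolerance = 1e-12)
  # k_last = 3 anchors one sample earlier
  s_exp <- dose_rate_samples(c(1, 4, 24, 72), 2 * exp(-0.03 * c(1, 4, 24, 72)))
  pw3 <- build_piecewise(s_exp, 3L, p)
  expect_equal(pw3$tx, 4)
  expect_equal(pw3$lambda_e, 0.03, tolerance = 1e-10)
  # single sample at t = 0: degenerate pure exponential with physical tail
  pw1 <- build_piecewise(dose_rate_samples(0, 1), 2L, p)
  expect_equal(pw1$tx, 0)
  expect_equal(pw1$lambda_e, p$phys_lambda)
})

test_that("piecewise dose of monoexponential samples converges with sampling", {
  p <- par_tumor()
  truth <- mono_dose_rate(1, 0.05)
  err <- vapply(list(c(1, 4, 24, 72), seq(0.5, 72, length.out = 16),
                     seq(0.05, 72, length.out = 64)),
                function(tt) {
    pw <- build_piecewise(truth_samples(truth, tt), 2L, p)
    abs(total_dose(pw) - total_dose(truth)) / total_dose(truth)
  }, numeric(1L))
  expect_true(all(diff(err) < 0))     # densification shrinks the error
  # the residual error is dominated by the zero-origin segment, which
  # shrinks with the first sample time
  expect_gt(err[1L] / err[3L], 5)
  expect_lt(err[3L], 2e-3)
})
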