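test_that("closed-form biexponential G matches the quadrature oracle", {
  p <- par_tumor()
  m <- biexp_dose_rate(2, 0.01, 0.1)
  g <- g_analytic_biexp(m, p)
  expect_equal(g, 0.0195989782693, tolerance = 1e-9)  # frozen oracle value
  expect_equal(g, g_oracle(m, p), tolerance = 1e-6)
  # no repair: fully interacting sublesions
  expect_equal(g_analytic_biexp(m, par_norepair()), 1)
  # scale invariance in r0
  expect_equal(g_analytic_biexp(biexp_dose_rate(77, 0.01, 0.1), p), g)
  expect_gt(g, 0); expect_lte(g, 1)
})

test_that("monoexponential G limit holds and matches the oracle", {
  p <- par_tumor()
  expect_equal(g_mono(p$mu, p), 0.5)
  expect_equal(g_mono(0.1, par_norepair()), 1)
  expect_equal(g_mono(0.1, p), 0.1 / (0.1 + log(2) / 1.5))
  expect_equal(g_oracle(mono_dose_rate(1, 0.1), p), g_mono(0.1, p),
               tolerance = 1e-6)
})

test_that("G decreases with repair rate and stays in (0, 1]", {
  m <- biexp_default()
  pw <- piecewise_fixture()
  mus <- c(0, 0.05, 0.2, 0.5, 1.4, 5)
  ga <- gh <- numeric(length(mus))
  for (i in seq_along(mus)) {
    p <- radiobio_params(10, mu = mus[i])
    ga[i] <- g_analytic_biexp(m, p)
    gh[i] <- g_hybrid(pw, p)$G
  }
  for (g in list(ga, gh)) {
    expect_true(all(diff(g) < 0))
    expect_true(all(g > 0 & g <= 1 + 1e-6))  # hybrid carries O(dt^2) error
  }
})

test_that("numerical recursion converges to the closed forms", {
  cfg <- integration_config(dt = 0.01, stop_time = 1000)
  p <- par_tumor()
  bd <- g_numerical(mono_dose_rate(1, 0.1), p, cfg)
  expect_s3_class(bd, "gfactor_breakdown")
  expect_false(bd$overflowed)
  expect_equal(bd$G, g_mono(0.1, p), tolerance = 1e-3)
  expect_equal(bd$D, 10, tolerance = 1e-6)
  expect_equal(bd$R0, bd$D^2 / 2)
  expect_lte(bd$R, bd$R0)

  m <- biexp_default()
  bd2 <- g_numerical(m, p, cfg)
  expect_equal(bd2$G, g_analytic_biexp(m, p), tolerance = 1e-3)
  expect_equal(bd2$D, 96, tolerance = 1e-6)
})

test_that("numerical R, D and EQD2 grow monotonically with stopping time", {
  p <- par_tumor()
  m <- biexp_default()
  ref <- compute_eqdx(m, p, engine = "analytic")
  stops <- c(100, 200, 400, 800)
  runs <- lapply(stops, function(s)
    g_numerical(m, p, integration_config(dt = 0.02, stop_time = s)))
  R <- vapply(runs, `[[`, 0, "R")
  D <- vapply(runs, `[[`, 0, "D")
  eq <- vapply(runs, function(b)
    eqdx_from_bed(bed(b$D, re_from_g(b$D, b$G, 10)), 2, 10), numeric(1L))
  expect_true(all(diff(R) > 0))
  expect_true(all(diff(D) > 0))
  expect_true(all(diff(eq) > 0))
  # bounded by the analytic value up to the dt = 0.02 trapezoid overshoot
  expect_true(all(eq <= ref$EQDX * (1 + 1e-5)))
})

test_that("overflow guard aborts the recursion as a structured signal", {
  p <- radiobio_params(10, trep = 0.5)  # mu*t > 700 at t ~ 505 h
  m <- biexp_default()
  cfg <- integration_config(dt = 0.05, stop_time = 600)
  expect_warning(bd <- g_numerical(m, p, cfg), class = "eqdx_overflow_warning")
  expect_true(bd$overflowed)
  expect_lt(bd$stop_time_used, 510)
  expect_gt(bd$stop_time_used, 495)
  # catchable condition carrying the partial breakdown
  err <- tryCatch(g_numerical(m, p, cfg, on_overflow = "error"),
                  eqdx_overflow_error = function(e) e)
  expect_s3_class(err, "eqdx_overflow_error")
  expect_equal(err$breakdown$G, bd$G)
})

test_that("auto-stop terminates once successive EQD2 values stabilise", {
  p <- par_tumor()
  cfg <- integration_config(dt = 0.02, stop_time = 1000, auto_stop = TRUE)
  bd <- g_numerical(mono_dose_rate(1, 0.1), p, cfg)
  expect_lt(bd$stop_time_used, 1000)
  expect_gte(bd$stop_time_used, 72)
  # converged to within the auto-stop band of the closed form
  expect_equal(bd$G, g_mono(0.1, p), tolerance = 5e-3)
})

test_that("hybrid engine reproduces the oracle and its exact limits", {
  p <- par_tumor()
  pw <- piecewise_fixture()
  bd <- g_hybrid(pw, p)
  expect_equal(bd$G, 0.0352162706608, tolerance = 1e-4)  # frozen oracle value
  expect_equal(bd$D, total_dose(pw))
  expect_equal(bd$R0, bd$D^2 / 2)
  expect_gte(bd$N, 0); expect_gte(bd$M, 0); expect_lte(bd$R, bd$R0)

  # tx = 0 degenerate model: exact monoexponential limit, N = M = 0
  pw0 <- piecewise_dose_rate(data.frame(t = 0, ddot = 1), tx = 0,
                             lambda_e = 0.1)
  bd0 <- g_hybrid(pw0, p)
  expect_identical(bd0$N, 0); expect_identical(bd0$M, 0)
  expect_equal(bd0$G, g_mono(0.1, p), tolerance = 1e-15)

  # repair-free limit
  expect_equal(g_hybrid(pw, par_norepair())$G, 1, tolerance = 1e-6)
})

test_that("halving the grid width moves the hybrid result by < 0.01%", {
  p <- par_tumor()
  pw <- piecewise_fixture()
  g1 <- g_hybrid(pw, p, integration_config(dt = 0.01))$G
  g2 <- g_hybrid(pw, p, integration_config(dt = 0.005))$G
  expect_lt(abs(g1 - g2) / g2, 1e-4)
  m <- biexp_default()
  n1 <- g_numerical(m, p, integration_config(dt = 0.01, stop_time = 300))$G
  n2 <- g_numerical(m, p, integration_config(dt = 0.005, stop_time = 300))$G
  expect_lt(abs(n1 - n2) / n2, 1e-4)
})

test_that("oracle accepts a plain function but then requires a horizon", {
  p <- par_tumor()
  fn <- function(t) exp(-0.1 * t)
  expect_error(g_oracle(fn, p), "horizon")
  expect_equal(g_oracle(fn, p, horizon = 400), g_mono(0.1, p),
               tolerance = 1e-6)
})
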