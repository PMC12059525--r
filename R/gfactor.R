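#' Integration settings for the numerical G-factor engines
#'
#' @param dt Time bin width for the trapezoid recursions, h. The default of
#'   0.01 h gives results that change by less than 0.01% when halved.
#' @param stop_time Termination (extrapolation) time for the fully numerical
#'   engine, h. When `auto_stop` is set this acts as a hard cap.
#' @param auto_stop If `TRUE`, the fully numerical engine increments its
#'   stopping time from `auto_stop_start` in steps of `auto_stop_step` until
#'   successive EQD2 values change by less than `auto_stop_rel_tol`.
#' @param auto_stop_start First candidate stopping time, h (default 72 h, the
#'   last clinical scan time).
#' @param auto_stop_step Stopping-time increment, h (default 10 h).
#' @param auto_stop_rel_tol Relative convergence tolerance (default 0.001,
#'   i.e. 0.1%).
#' @return An object of class `"integration_config"`.
#' @export
integration_config <- function(dt = 0.01, stop_time = 2000,
                               auto_stop = FALSE, auto_stop_start = 72,
                               auto_stop_step = 10,
                               auto_stop_rel_tol = 0.001) {
  stopifnot(dt > 0, stop_time > 0, auto_stop_start > 0, auto_stop_step > 0,
            auto_stop_rel_tol > 0, auto_stop_rel_tol < 1)
  structure(list(dt = dt, stop_time = stop_time, auto_stop = auto_stop,
                 auto_stop_start = auto_stop_start,
                 auto_stop_step = auto_stop_step,
                 auto_stop_rel_tol = auto_stop_rel_tol),
            class = "integration_config")
}

# exp(mu * t) is evaluated literally in the published recursion; beyond
# mu*t ~ 709.78 it is Inf in double precision.  Guard with a safety margin.
OVERFLOW_MU_T <- 700

# cumulative trapezoid integral of y(t) on a (possibly nonuniform) grid
trapz_cum <- function(t, y) {
  n <- length(t)
  if (n < 2L) return(numeric(n))
  c(0, cumsum(diff(t) * (y[-n] + y[-1L]) / 2))
}

new_gfactor_breakdown <- function(N, M, R, R0, D, G, stop_time_used,
                                  overflowed, engine) {
  structure(list(N = N, M = M, R = R, R0 = R0, D = D, G = G,
                 stop_time_used = stop_time_used, overflowed = overflowed,
                 engine = engine),
            class = "gfactor_breakdown")
}

#' @export
print.gfactor_breakdown <- function(x, ...) {
  cat(sprintf("<gfactor_breakdown> engine = %s\n", x$engine))
  cat(sprintf("  G = %.6g, D = %.6g Gy\n", x$G, x$D))
  cat(sprintf("  R = %.6g, R0 = D^2/2 = %.6g, N = %.6g, M = %.6g\n",
              x$R, x$R0, x$N, x$M))
  cat(sprintf("  stop time used = %g h, overflowed = %s\n",
              x$stop_time_used, x$overflowed))
  invisible(x)
}

#' Closed-form G factor for a biexponential dose-rate curve
#'
#' For \eqn{\dot D(t) = r_0(e^{-\lambda_{e1} t} - e^{-\lambda_{e2} t})} with
#' monoexponential repair at rate \eqn{\mu}, the Lea-Catcheside protraction
#' factor has the closed form
#' \deqn{G = \frac{\lambda_{e1}\lambda_{e2}
#'   (\lambda_{e1}+\lambda_{e2}+\mu)}{(\lambda_{e1}+\lambda_{e2})
#'   (\lambda_{e1}+\mu)(\lambda_{e2}+\mu)}.}
#' The result does not depend on the amplitude \eqn{r_0} and lies in
#' \eqn{(0, 1]}; \eqn{\mu = 0} (no repair) gives exactly 1.
#'
#' @param model A [biexp_dose_rate()] object.
#' @param params A [radiobio_params()] object (only `mu` is used).
#' @return The G factor, dimensionless.
#' @examples
#' p <- radiobio_params(alpha_beta = 10, trep = 1.5)
#' g_analytic_biexp(biexp_dose_rate(2, 0.01, 0.1), p)  # ~0.0196
#' @export
g_analytic_biexp <- function(model, params) {
  stopifnot(inherits(model, "biexp_dose_rate"),
            inherits(params, "radiobio_params"))
  l1 <- model$lambda_e1; l2 <- model$lambda_e2; mu <- params$mu
  l1 * l2 * (l1 + l2 + mu) / ((l1 + l2) * (l1 + mu) * (l2 + mu))
}

#' G factor for single-phase exponential decay
#'
#' The well-known monoexponential limit \eqn{G = \lambda_e/(\lambda_e+\mu)}.
#'
#' @param lambda_e Effective decay constant of the dose-rate curve, 1/h.
#' @param params A [radiobio_params()] object (only `mu` is used).
#' @return The G factor, dimensionless.
#' @export
g_mono <- function(lambda_e, params) {
  stopifnot(inherits(params, "radiobio_params"), lambda_e > 0)
  lambda_e / (lambda_e + params$mu)
}

# Core of the fully numerical engine: trapezoid recursions
#   M(m) = M(m-1) + (Ddot_m e^{mu t_m} + Ddot_{m-1} e^{mu t_{m-1}})/2 * dt
#   N(m) = N(m-1) + (Ddot_m M_m e^{-mu t_m}
#                    + Ddot_{m-1} M_{m-1} e^{-mu t_{m-1}})/2 * dt
# on a given grid, together with the running trapezoid total dose.  The
# recursions are cumulative sums, so the whole profile over stopping times
# comes out of one pass.  Aborts at the overflow guard.
numerical_grid <- function(ddot, params, t) {
  mu <- params$mu
  overflowed <- FALSE
  if (mu > 0 && mu * t[length(t)] > OVERFLOW_MU_T) {
    keep <- t <= OVERFLOW_MU_T / mu
    t <- t[keep]
    overflowed <- TRUE
  }
  d <- ddot(t)
  egrow <- exp(mu * t)
  M <- trapz_cum(t, d * egrow)
  N <- trapz_cum(t, d * M * exp(-mu * t))
  D <- trapz_cum(t, d)
  list(t = t, d = d, M = M, N = N, D = D, overflowed = overflowed)
}

eqd2_from_DN <- function(D, N, alpha_beta, X = 2) {
  (D + 2 * N / alpha_beta) / (1 + X / alpha_beta)
}

#' Fully numerical G factor by trapezoid recursion
#'
#' Dynamic-programming evaluation of the protraction double integral on a
#' uniform grid (Hobbs-Sgouros recursion): the inner integral `M` accumulates
#' \eqn{\dot D(t) e^{\mu t}}, the outer integral `N` accumulates
#' \eqn{\dot D(t) M(t) e^{-\mu t}}, and \eqn{G = N/(D^2/2)} with the total
#' dose `D` obtained by trapezoid integration on the same grid.
#'
#' The recursion evaluates the growing exponential \eqn{e^{\mu t}} literally,
#' so it overflows once \eqn{\mu t} approaches 709.78 (the log of the largest
#' double). A guard aborts the recursion at \eqn{\mu t > 700}, flags the
#' result, and reports the last completed stopping time; set
#' `on_overflow = "error"` to turn this into a catchable condition of class
#' `"eqdx_overflow_error"` carrying the partial breakdown in its `$breakdown`
#' field.
#'
#' With `cfg$auto_stop` the stopping time is incremented from
#' `auto_stop_start` in `auto_stop_step` steps until successive EQD2 values
#' change by less than `auto_stop_rel_tol` (or the cap / overflow guard is
#' reached).
#'
#' @param ddot A dose-rate model or a vectorised function of time (h)
#'   returning Gy/h.
#' @param params A [radiobio_params()] object.
#' @param cfg An [integration_config()] object.
#' @param on_overflow `"flag"` (default: classed warning, partial result
#'   returned) or `"error"` (classed condition raised).
#' @return A `gfactor_breakdown` with fields `N`, `M`, `R`, `R0`, `D`, `G`,
#'   `stop_time_used`, `overflowed`.
#' @export
g_numerical <- function(ddot, params, cfg = integration_config(),
                        on_overflow = c("flag", "error")) {
  on_overflow <- match.arg(on_overflow)
  stopifnot(inherits(params, "radiobio_params"),
            inherits(cfg, "integration_config"))
  if (inherits(ddot, "dose_rate_model")) ddot <- dose_rate_fun(ddot)
  t <- seq(0, cfg$stop_time, by = cfg$dt)
  gr <- numerical_grid(ddot, params, t)
  n <- length(gr$t)
  stop_used <- gr$t[n]

  if (cfg$auto_stop) {
    checkpoints <- seq(cfg$auto_stop_start, gr$t[n], by = cfg$auto_stop_step)
    if (length(checkpoints) >= 2L) {
      idx <- findInterval(checkpoints, gr$t)
      eq <- eqd2_from_DN(gr$D[idx], gr$N[idx], params$alpha_beta)
      rel <- abs(diff(eq)) / eq[-1L]
      hit <- which(rel < cfg$auto_stop_rel_tol)
      if (length(hit)) {
        n <- idx[hit[1L] + 1L]
        stop_used <- gr$t[n]
      }
    }
  }

  bd <- new_gfactor_breakdown(
    N = gr$N[n], M = gr$M[n], R = gr$N[n], R0 = gr$D[n]^2 / 2,
    D = gr$D[n], G = gr$N[n] / (gr$D[n]^2 / 2),
    stop_time_used = stop_used, overflowed = gr$overflowed,
    engine = "numerical"
  )
  if (gr$overflowed) {
    msg <- sprintf(
      "numerical G-factor recursion aborted at t = %.6g h: exp(mu*t) would overflow (mu*t > %g); partial result reported",
      stop_used, OVERFLOW_MU_T)
    if (on_overflow == "error") {
      cond <- structure(
        class = c("eqdx_overflow_error", "error", "condition"),
        list(message = msg, call = sys.call(-1L), breakdown = bd))
      stop(cond)
    }
    warning(structure(
      class = c("eqdx_overflow_warning", "warning", "condition"),
      list(message = msg, call = sys.call(-1L))))
  }
  bd
}

#' Hybrid numerical-analytical G factor for piecewise dose-rate curves
#'
#' Splits the protraction double integral at the tail anchor time
#' \eqn{t_x}: the linear-interpolation head on \eqn{[0, t_x]} is handled by
#' the trapezoid recursions (interim values `N` and `M`), and the
#' monoexponential tail is integrated analytically, giving
#' \deqn{G = \frac{2}{D^2}\left[N
#'   + \frac{M \dot D(t_x) e^{-\mu t_x}}{\lambda_e+\mu}
#'   + \frac{\dot D^2(t_x)}{2\lambda_e(\lambda_e+\mu)}\right].}
#' The three terms count sublethal-lesion pairs with both, one, and neither
#' hit before \eqn{t_x}. No extrapolation beyond \eqn{t_x} is ever needed,
#' and \eqn{\mu t_x} is bounded by the scan schedule, so the growing
#' exponential cannot overflow in practice.
#'
#' For a degenerate model with \eqn{t_x = 0} (pure exponential) the head
#' vanishes and the expression reduces algebraically to
#' \eqn{\lambda_e/(\lambda_e+\mu)}.
#'
#' @param model A [piecewise_dose_rate()] object.
#' @param params A [radiobio_params()] object.
#' @param cfg An [integration_config()] object; only `dt` is used, for the
#'   head grid (sample times are always included as grid knots).
#' @return A `gfactor_breakdown`; `stop_time_used` is `tx`.
#' @export
g_hybrid <- function(model, params, cfg = integration_config()) {
  stopifnot(inherits(model, "piecewise_dose_rate"),
            inherits(params, "radiobio_params"),
            inherits(cfg, "integration_config"))
  mu <- params$mu; le <- model$lambda_e
  tx <- model$tx; dtx <- model$ddot_tx
  if (tx > 0) {
    t <- sort(unique(c(seq(0, tx, by = cfg$dt), model$samples$t, tx)))
    gr <- numerical_grid(dose_rate_fun(model), params, t)
    n <- length(gr$t)
    N <- gr$N[n]; M <- gr$M[n]
  } else {
    N <- 0; M <- 0
  }
  R <- N + M * dtx * exp(-mu * tx) / (le + mu) +
    dtx^2 / (2 * le * (le + mu))
  D <- total_dose(model)
  new_gfactor_breakdown(
    N = N, M = M, R = R, R0 = D^2 / 2, D = D, G = 2 * R / D^2,
    stop_time_used = tx, overflowed = FALSE, engine = "hybrid"
  )
}

#' Brute-force double-quadrature oracle for the G factor
#'
#' Independent evaluation of the protraction factor
#' \deqn{G = \frac{\int_0^\infty \dot D(t)\int_0^t \dot D(t')
#'   e^{-\mu(t-t')}\,dt'\,dt}{D^2/2}}
#' by nested adaptive quadrature ([stats::integrate()]), with the total dose
#' `D` also obtained by quadrature. Intended for validation and testing; it
#' shares no code path with the fast engines.
#'
#' The outer integral is split at the model's knot times (piecewise segment
#' boundaries) and a fixed set of tail break points; the inner integral is
#' restricted to the support of the repair kernel (contributions older than
#' \eqn{60/\mu} are below the absolute tolerance).
#'
#' @param model A dose-rate model, or a vectorised dose-rate function of time
#'   (in which case `horizon` must be given and `knots` may be).
#' @param params A [radiobio_params()] object.
#' @param horizon Upper limit of the outer integral, h. Defaults to
#'   `max(2000, 40/lambda_slowest)` so the truncated tail is negligible.
#' @param knots Times at which the dose-rate function is non-smooth.
#' @param rel_tol,abs_tol Quadrature tolerances per nested integral.
#' @return The G factor, dimensionless.
#' @export
g_oracle <- function(model, params, horizon = NULL, knots = NULL,
                     rel_tol = 1e-9, abs_tol = 1e-12) {
  stopifnot(inherits(params, "radiobio_params"))
  mu <- params$mu
  if (inherits(model, "dose_rate_model")) {
    fn <- dose_rate_fun(model)
    slowest <- switch(class(model)[1L],
      biexp_dose_rate = model$lambda_e1,
      mono_dose_rate = model$lambda_e,
      piecewise_dose_rate = model$lambda_e)
    if (is.null(horizon)) horizon <- max(2000, 40 / slowest)
    if (is.null(knots) && inherits(model, "piecewise_dose_rate"))
      knots <- c(model$samples$t, model$tx)
  } else {
    fn <- model
    if (is.null(horizon))
      stop("`horizon` must be supplied for a plain dose-rate function",
           call. = FALSE)
  }
  knots <- sort(unique(c(0, knots, horizon)))
  knots <- knots[knots >= 0 & knots <= horizon]

  quad <- function(f, lo, hi) {
    if (hi - lo < 1e-14) return(0)
    stats::integrate(f, lo, hi, rel.tol = rel_tol, abs.tol = abs_tol,
                     subdivisions = 500L, stop.on.error = TRUE)$value
  }
  split_quad <- function(f, lo, hi, brk) {
    brk <- sort(unique(c(lo, brk[brk > lo & brk < hi], hi)))
    s <- 0
    for (i in seq_len(length(brk) - 1L)) s <- s + quad(f, brk[i], brk[i + 1L])
    s
  }

  inner <- function(t) {
    if (t <= 0) return(0)
    lo <- if (mu > 0) max(0, t - 60 / mu) else 0
    split_quad(function(s) fn(s) * exp(-mu * (t - s)), lo, t, knots)
  }
  tail_breaks <- c(10, 30, 100, 300, 1000, 3000)
  outer_fn <- function(tv) fn(tv) * vapply(tv, inner, numeric(1L))
  R <- split_quad(outer_fn, 0, horizon, c(knots, tail_breaks))
  D <- split_quad(fn, 0, horizon, c(knots, tail_breaks))
  R / (D^2 / 2)
}
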