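#' Relative effectiveness from dose and protraction factor
#'
#' Under the linear-quadratic model the relative effectiveness of a
#' protracted irradiation is \deqn{RE = 1 + \frac{G\,D}{\alpha/\beta},}
#' converting the absorbed dose D into the biologically effective dose
#' \eqn{BED = D \cdot RE}.
#'
#' @param D Total absorbed dose, Gy; nonnegative.
#' @param G Lea-Catcheside protraction factor, in `[0, 1]`.
#' @param alpha_beta Radiosensitivity ratio, Gy; positive.
#' @return Relative effectiveness, dimensionless, always >= 1.
#' @export
re_from_g <- function(D, G, alpha_beta) {
  stopifnot(all(D >= 0), all(G >= -1e-12), all(G <= 1 + 1e-9),
            alpha_beta > 0)
  1 + G * D / alpha_beta
}

#' Biologically effective dose
#'
#' `BED = D * RE`; the total dose of infinitely small fractions (or
#' infinitely low dose rate) producing the same log cell kill.
#'
#' @param D Total absorbed dose, Gy.
#' @param RE Relative effectiveness, >= 1.
#' @return BED in Gy.
#' @export
bed <- function(D, RE) {
  stopifnot(all(D >= 0), all(RE >= 1 - 1e-12))
  D * RE
}

#' Equieffective dose in X-Gy fractions from BED
#'
#' \deqn{EQDX = \frac{BED}{1 + X/(\alpha/\beta)}.}
#' Ratios of two EQDX values at the same `(X, alpha_beta)` equal ratios of
#' their BEDs (the fraction-size denominator cancels), so relative
#' comparisons are independent of the reference fraction size.
#'
#' @param BED Biologically effective dose, Gy.
#' @param X Reference dose per fraction, Gy (2 for EQD2; 0 recovers BED).
#' @param alpha_beta Radiosensitivity ratio, Gy.
#' @return EQDX in Gy.
#' @export
eqdx_from_bed <- function(BED, X, alpha_beta) {
  stopifnot(all(BED >= 0), X >= 0, alpha_beta > 0)
  BED / (1 + X / alpha_beta)
}

#' Equieffective dose for a fractionated external-beam schedule
#'
#' For acute fractions of size `d` delivering total dose `D`,
#' \deqn{EQDX = D\,\frac{1 + d/(\alpha/\beta)}{1 + X/(\alpha/\beta)}.}
#'
#' @param D Total absorbed dose, Gy.
#' @param d Test dose per fraction, Gy.
#' @param X Reference dose per fraction, Gy.
#' @param alpha_beta Radiosensitivity ratio, Gy.
#' @return EQDX in Gy.
#' @export
eqdx_ebrt <- function(D, d, X, alpha_beta) {
  stopifnot(all(D >= 0), all(d >= 0), X >= 0, alpha_beta > 0)
  D * (1 + d / alpha_beta) / (1 + X / alpha_beta)
}

#' Relative effectiveness of a biexponential dose-rate curve, direct form
#'
#' Evaluates RE in the single expanded expression
#' \deqn{RE = 1 + \frac{r_0(\lambda_{e1}+\lambda_{e2}+\mu)
#'   (\lambda_{e2}-\lambda_{e1})}{(\lambda_{e1}+\lambda_{e2})
#'   (\lambda_{e1}+\mu)(\lambda_{e2}+\mu)\,\alpha/\beta},}
#' which is algebraically identical to assembling
#' `re_from_g(total_dose(model), g_analytic_biexp(model, params), ...)`.
#' Kept as a separate route so the identity can be checked, and as the
#' cheapest possible evaluation for voxel-scale use.
#'
#' @param model A [biexp_dose_rate()] object.
#' @param params A [radiobio_params()] object.
#' @return Relative effectiveness, dimensionless.
#' @export
re_analytic_biexp <- function(model, params) {
  stopifnot(inherits(model, "biexp_dose_rate"),
            inherits(params, "radiobio_params"))
  l1 <- model$lambda_e1; l2 <- model$lambda_e2; mu <- params$mu
  1 + model$r0 * (l1 + l2 + mu) * (l2 - l1) /
    ((l1 + l2) * (l1 + mu) * (l2 + mu) * params$alpha_beta)
}

#' Relative effectiveness from a hybrid-engine breakdown, direct form
#'
#' Evaluates \deqn{RE = 1 + \frac{2}{D\,\alpha/\beta}\left[N
#'   + \frac{M \dot D(t_x) e^{-\mu t_x}}{\lambda_e+\mu}
#'   + \frac{\dot D^2(t_x)}{2\lambda_e(\lambda_e+\mu)}\right]
#'   = 1 + \frac{2R}{D\,\alpha/\beta}}
#' directly from the interim values of a [g_hybrid()] breakdown; identical to
#' `re_from_g(bd$D, bd$G, alpha_beta)`.
#'
#' @param breakdown A `gfactor_breakdown` from [g_hybrid()].
#' @param params A [radiobio_params()] object.
#' @return Relative effectiveness, dimensionless.
#' @export
re_hybrid <- function(breakdown, params) {
  stopifnot(inherits(breakdown, "gfactor_breakdown"),
            inherits(params, "radiobio_params"))
  1 + 2 * breakdown$R / (breakdown$D * params$alpha_beta)
}

new_eqdx_result <- function(D, G, params, X, engine,
                            stop_time_used = NA_real_, overflowed = FALSE) {
  RE <- re_from_g(D, G, params$alpha_beta)
  BED <- bed(D, RE)
  structure(
    list(D = D, G = G, RE = RE, BED = BED,
         EQDX = eqdx_from_bed(BED, X, params$alpha_beta),
         X = X, alpha_beta = params$alpha_beta, engine = engine,
         stop_time_used = stop_time_used, overflowed = overflowed),
    class = "eqdx_result"
  )
}

#' @export
print.eqdx_result <- function(x, ...) {
  cat(sprintf("<eqdx_result> engine = %s\n", x$engine))
  cat(sprintf("  D = %.4f Gy, G = %.6f, RE = %.4f\n", x$D, x$G, x$RE))
  cat(sprintf("  BED = %.4f Gy, EQD%g (alpha/beta = %g Gy) = %.4f Gy\n",
              x$BED, x$X, x$alpha_beta, x$EQDX))
  if (isTRUE(x$overflowed))
    cat(sprintf("  [overflow guard fired; stopped at %g h]\n",
                x$stop_time_used))
  invisible(x)
}

#' Compute EQDX for a dose-rate model with a chosen G-factor engine
#'
#' One-stop composition D -> G -> RE -> BED -> EQDX. Engine applicability:
#' `"analytic"` requires a biexponential (closed form) or monoexponential
#' (\eqn{\lambda_e/(\lambda_e+\mu)}) model; `"hybrid"` a piecewise or
#' monoexponential model; `"numerical"` and `"oracle"` accept any model.
#'
#' @param model A dose-rate model.
#' @param params A [radiobio_params()] object.
#' @param X Reference dose per fraction, Gy (default 2, i.e. EQD2).
#' @param engine One of `"analytic"`, `"hybrid"`, `"numerical"`, `"oracle"`.
#' @param cfg An [integration_config()]; used by the hybrid and numerical
#'   engines.
#' @param n_cycles Number of identically delivered, well-separated treatment
#'   cycles; D, BED and EQDX scale linearly (full inter-cycle repair assumed,
#'   no interaction term), G and RE are per-cycle quantities.
#' @return An `eqdx_result` with fields `D`, `G`, `RE`, `BED`, `EQDX`, `X`,
#'   `alpha_beta`, `engine`, `stop_time_used`, `overflowed`.
#' @examples
#' p <- radiobio_params(alpha_beta = 10, trep = 1.5)
#' m <- biexp_dose_rate(2, 0.02, 0.5)
#' compute_eqdx(m, p, X = 2, engine = "analytic")
#' @export
compute_eqdx <- function(model, params, X = 2,
                         engine = c("analytic", "hybrid", "numerical",
                                    "oracle"),
                         cfg = integration_config(), n_cycles = 1L) {
  engine <- match.arg(engine)
  stopifnot(inherits(model, "dose_rate_model"),
            inherits(params, "radiobio_params"), n_cycles >= 1L)
  stop_used <- NA_real_; overflowed <- FALSE
  if (engine == "analytic") {
    if (inherits(model, "biexp_dose_rate")) {
      G <- g_analytic_biexp(model, params)
    } else if (inherits(model, "mono_dose_rate")) {
      G <- g_mono(model$lambda_e, params)
    } else {
      stop("engine 'analytic' requires a biexponential or monoexponential ",
           "model; use 'hybrid' or 'numerical' for piecewise curves",
           call. = FALSE)
    }
    D <- total_dose(model)
  } else if (engine == "hybrid") {
    if (inherits(model, "mono_dose_rate")) {
      G <- g_mono(model$lambda_e, params)
      D <- total_dose(model)
    } else if (inherits(model, "piecewise_dose_rate")) {
      bd <- g_hybrid(model, params, cfg)
      G <- bd$G; D <- bd$D; stop_used <- bd$stop_time_used
    } else {
      stop("engine 'hybrid' requires a piecewise or monoexponential model; ",
           "use 'analytic' for biexponential curves", call. = FALSE)
    }
  } else if (engine == "numerical") {
    bd <- withCallingHandlers(
      g_numerical(model, params, cfg),
      eqdx_overflow_warning = function(w) invokeRestart("muffleWarning"))
    G <- bd$G; D <- bd$D
    stop_used <- bd$stop_time_used; overflowed <- bd$overflowed
  } else {
    G <- g_oracle(model, params)
    D <- total_dose(model)
  }
  res <- new_eqdx_result(D, G, params, X, engine, stop_used, overflowed)
  if (n_cycles > 1L) {
    res$D <- res$D * n_cycles
    res$BED <- res$BED * n_cycles
    res$EQDX <- res$EQDX * n_cycles
  }
  res
}
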