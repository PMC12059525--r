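#' Radiobiological parameter set
#'
#' Bundles the linear-quadratic and pharmacokinetic constants needed by every
#' G-factor engine: the tissue radiosensitivity ratio \eqn{\alpha/\beta}, the
#' sublethal-damage repair half-time \eqn{T_{rep}} (equivalently the repair
#' rate constant \eqn{\mu = \ln 2 / T_{rep}} of the monoexponential repair
#' kernel \eqn{\psi(t) = e^{-\mu t}}), and the physical half-life of the
#' radionuclide (equivalently its decay constant \eqn{\lambda}).
#'
#' All times are hours, all rate constants 1/h, all doses Gy.
#'
#' @param alpha_beta Tissue radiosensitivity ratio \eqn{\alpha/\beta} in Gy
#'   (typically ~10 Gy for tumors, ~3 Gy for late-responding normal tissue).
#' @param trep Repair half-time in hours. `Inf` is allowed and corresponds to
#'   no repair (\eqn{\mu = 0}). Exactly one of `trep` and `mu` must be given.
#' @param mu Repair rate constant in 1/h; alternative to `trep`.
#' @param phys_half_life Physical half-life of the radionuclide in hours.
#'   Defaults to 159.528 h (6.647 d), the literature value for Lu-177.
#' @return An object of class `"radiobio_params"`: a list with elements
#'   `alpha_beta`, `trep`, `mu`, `phys_half_life`, `phys_lambda`.
#' @examples
#' radiobio_params(alpha_beta = 10, trep = 1.5)
#' @export
radiobio_params <- function(alpha_beta, trep = NULL, mu = NULL,
                            phys_half_life = 159.528) {
  if (!is.numeric(alpha_beta) || length(alpha_beta) != 1L || alpha_beta <= 0)
    stop("`alpha_beta` must be a single positive number (Gy)", call. = FALSE)
  if (is.null(trep) && is.null(mu))
    stop("supply one of `trep` (h) or `mu` (1/h)", call. = FALSE)
  if (!is.null(trep) && !is.null(mu) &&
      abs(mu - log(2) / trep) > 1e-12 * max(mu, 1))
    stop("`trep` and `mu` are inconsistent; supply only one", call. = FALSE)
  if (is.null(mu)) {
    if (trep <= 0) stop("`trep` must be positive", call. = FALSE)
    mu <- log(2) / trep
  } else {
    if (mu < 0) stop("`mu` must be nonnegative", call. = FALSE)
    trep <- log(2) / mu  # Inf when mu == 0
  }
  if (phys_half_life <= 0)
    stop("`phys_half_life` must be positive", call. = FALSE)
  structure(
    list(alpha_beta = alpha_beta, trep = trep, mu = mu,
         phys_half_life = phys_half_life,
         phys_lambda = log(2) / phys_half_life),
    class = "radiobio_params"
  )
}

#' @export
print.radiobio_params <- function(x, ...) {
  cat("Radiobiological parameters\n")
  cat(sprintf("  alpha/beta      : %g Gy\n", x$alpha_beta))
  cat(sprintf("  repair half-time: %g h (mu = %g 1/h)\n", x$trep, x$mu))
  cat(sprintf("  phys. half-life : %g h (lambda = %g 1/h)\n",
              x$phys_half_life, x$phys_lambda))
  invisible(x)
}

#' Dose-rate measurement samples
#'
#' Validates and assembles a set of post-injection dose-rate measurements
#' into a data frame with columns `t` (hours post-injection) and `ddot`
#' (mean absorbed dose rate, Gy/h), sorted by time.
#'
#' @param t Numeric vector of measurement times, h; all nonnegative, distinct.
#' @param ddot Numeric vector of absorbed dose rates, Gy/h; all nonnegative.
#' @return A data frame of class `"dose_rate_samples"`.
#' @export
dose_rate_samples <- function(t, ddot) {
  if (length(t) != length(ddot))
    stop("`t` and `ddot` must have the same length", call. = FALSE)
  if (any(!is.finite(t)) || any(t < 0))
    stop("sample times must be finite and nonnegative", call. = FALSE)
  if (any(!is.finite(ddot)) || any(ddot < 0))
    stop("dose rates must be finite and nonnegative (negative rates from ",
         "noisy reconstruction must be resolved upstream, not clamped)",
         call. = FALSE)
  o <- order(t)
  t <- t[o]; ddot <- ddot[o]
  if (anyDuplicated(t))
    stop("sample times must be distinct", call. = FALSE)
  structure(data.frame(t = t, ddot = ddot),
            class = c("dose_rate_samples", "data.frame"))
}

as_dose_rate_samples <- function(x) {
  if (inherits(x, "dose_rate_samples")) return(x)
  if (is.data.frame(x) && all(c("t", "ddot") %in% names(x)))
    return(dose_rate_samples(x$t, x$ddot))
  stop("expected a dose_rate_samples object or a data frame with columns ",
       "`t` and `ddot`", call. = FALSE)
}

#' Biexponential absorbed dose-rate model
#'
#' The standard dose-rate model for radiopharmaceutical therapy,
#' \deqn{\dot D(t) = r_0 (e^{-\lambda_{e1} t} - e^{-\lambda_{e2} t}),}
#' where the effective rate constants fold together biological clearance and
#' physical decay. The equal-and-opposite amplitudes encode the assumption
#' \eqn{\dot D(0) = 0} (activity builds up from zero at injection). The
#' constraint \eqn{0 < \lambda_{e1} < \lambda_{e2}} guarantees a nonnegative
#' dose rate with a single interior maximum.
#'
#' @param r0 Amplitude, Gy/h; positive.
#' @param lambda_e1 Slow effective rate constant, 1/h.
#' @param lambda_e2 Fast effective rate constant, 1/h; must exceed
#'   `lambda_e1` by at least a relative gap of 1e-6 (the degenerate equal-rate
#'   model is identically zero).
#' @return An object of class `c("biexp_dose_rate", "dose_rate_model")`.
#' @seealso [biexp_from_biological()] to construct from biological clearance
#'   rates plus a physical decay constant.
#' @examples
#' m <- biexp_dose_rate(r0 = 2, lambda_e1 = 0.02, lambda_e2 = 0.5)
#' dose_rate(m, c(0, 4, 24))
#' total_dose(m)  # 96 Gy
#' @export
biexp_dose_rate <- function(r0, lambda_e1, lambda_e2) {
  if (!is.finite(r0) || r0 <= 0)
    stop("`r0` must be positive", call. = FALSE)
  if (!is.finite(lambda_e1) || lambda_e1 <= 0)
    stop("`lambda_e1` must be positive", call. = FALSE)
  if (!is.finite(lambda_e2) || lambda_e2 <= lambda_e1 * (1 + 1e-6))
    stop("`lambda_e2` must exceed `lambda_e1` (relative gap >= 1e-6); ",
         "the degenerate equal-rate model has identically zero dose rate",
         call. = FALSE)
  structure(list(r0 = r0, lambda_e1 = lambda_e1, lambda_e2 = lambda_e2),
            class = c("biexp_dose_rate", "dose_rate_model"))
}

#' Biexponential model from biological clearance rates
#'
#' Convenience constructor taking the biological clearance parameterisation
#' \eqn{\dot D(t) = A(e^{-\lambda_1 t} - e^{-\lambda_2 t}) e^{-\lambda t}}
#' and folding the physical decay constant \eqn{\lambda} into effective rates
#' \eqn{\lambda_{ei} = \lambda_i + \lambda}.
#'
#' @param A Amplitude, Gy/h (becomes `r0`).
#' @param lambda1,lambda2 Biological clearance rate constants, 1/h;
#'   nonnegative, `lambda1 < lambda2`.
#' @param params A [radiobio_params()] object supplying the physical decay
#'   constant.
#' @return A [biexp_dose_rate()] object.
#' @export
biexp_from_biological <- function(A, lambda1, lambda2, params) {
  stopifnot(inherits(params, "radiobio_params"))
  if (lambda1 < 0 || lambda2 < 0)
    stop("biological clearance rates must be nonnegative", call. = FALSE)
  biexp_dose_rate(A, lambda1 + params$phys_lambda,
                  lambda2 + params$phys_lambda)
}

#' Monoexponential absorbed dose-rate model
#'
#' \eqn{\dot D(t) = \dot d_0 e^{-\lambda_e t}}: single-phase decay at the
#' effective rate \eqn{\lambda_e} (biological clearance plus physical decay).
#'
#' @param d0 Initial dose rate, Gy/h; positive.
#' @param lambda_e Effective decay constant, 1/h; positive.
#' @return An object of class `c("mono_dose_rate", "dose_rate_model")`.
#' @export
mono_dose_rate <- function(d0, lambda_e) {
  if (!is.finite(d0) || d0 <= 0) stop("`d0` must be positive", call. = FALSE)
  if (!is.finite(lambda_e) || lambda_e <= 0)
    stop("`lambda_e` must be positive", call. = FALSE)
  structure(list(d0 = d0, lambda_e = lambda_e),
            class = c("mono_dose_rate", "dose_rate_model"))
}

#' Piecewise linear-exponential absorbed dose-rate model
#'
#' Linear interpolation through the measured samples up to the tail anchor
#' time `tx`, then monoexponential decay
#' \eqn{\dot D(t) = \dot D(t_x) e^{-\lambda_e (t - t_x)}} beyond. If the first
#' sample is at \eqn{t > 0}, a segment from \eqn{(0, 0)} to it is prepended,
#' consistent with the zero initial dose rate assumed for systemic therapy.
#' Samples recorded after `tx` (if any) play no part in the curve; the tail
#' is fully determined by `tx` and `lambda_e`.
#'
#' @param samples A [dose_rate_samples()] object (or data frame with columns
#'   `t`, `ddot`).
#' @param tx Tail anchor time, h; must equal the time of one of the samples
#'   (or 0 for a degenerate pure-exponential model anchored at the dose rate
#'   of a sample at t = 0).
#' @param lambda_e Tail effective decay constant, 1/h; positive.
#' @return An object of class `c("piecewise_dose_rate", "dose_rate_model")`
#'   with elements `samples` (including any prepended origin), `tx`,
#'   `lambda_e`, `ddot_tx`.
#' @seealso [build_piecewise()] which assembles this model from raw samples,
#'   estimating `lambda_e` from the final measurements.
#' @export
piecewise_dose_rate <- function(samples, tx, lambda_e) {
  samples <- as_dose_rate_samples(samples)
  if (!is.finite(lambda_e) || lambda_e <= 0)
    stop("`lambda_e` must be positive", call. = FALSE)
  if (!any(abs(samples$t - tx) < 1e-12))
    stop("`tx` must coincide with one of the sample times", call. = FALSE)
  if (samples$t[1L] > 0)
    samples <- dose_rate_samples(c(0, samples$t), c(0, samples$ddot))
  head <- samples[samples$t <= tx + 1e-12, , drop = FALSE]
  ddot_tx <- head$ddot[nrow(head)]
  structure(list(samples = head, tx = tx, lambda_e = lambda_e,
                 ddot_tx = ddot_tx),
            class = c("piecewise_dose_rate", "dose_rate_model"))
}

#' Evaluate an absorbed dose-rate model
#'
#' @param model A dose-rate model (`biexp_dose_rate`, `mono_dose_rate`, or
#'   `piecewise_dose_rate`).
#' @param t Numeric vector of times post-injection, h; nonnegative.
#' @return Absorbed dose rate(s) in Gy/h, same length as `t`.
#' @export
dose_rate <- function(model, t) UseMethod("dose_rate")

check_times <- function(t) {
  if (any(!is.finite(t)) || any(t < 0))
    stop("evaluation times must be finite and nonnegative", call. = FALSE)
  t
}

#' @rdname dose_rate
#' @export
dose_rate.biexp_dose_rate <- function(model, t) {
  t <- check_times(t)
  model$r0 * (exp(-model$lambda_e1 * t) - exp(-model$lambda_e2 * t))
}

#' @rdname dose_rate
#' @export
dose_rate.mono_dose_rate <- function(model, t) {
  t <- check_times(t)
  model$d0 * exp(-model$lambda_e * t)
}

#' @rdname dose_rate
#' @export
dose_rate.piecewise_dose_rate <- function(model, t) {
  t <- check_times(t)
  out <- numeric(length(t))
  head_idx <- t <= model$tx
  if (any(head_idx)) {
    s <- model$samples
    out[head_idx] <- if (nrow(s) == 1L) s$ddot else
      stats::approx(s$t, s$ddot, xout = t[head_idx], rule = 2L)$y
  }
  if (any(!head_idx)) {
    out[!head_idx] <-
      model$ddot_tx * exp(-model$lambda_e * (t[!head_idx] - model$tx))
  }
  out
}

#' Coerce a dose-rate model to a plain function of time
#'
#' @param model A dose-rate model.
#' @return A vectorised function `function(t)` returning Gy/h.
#' @export
dose_rate_fun <- function(model) {
  force(model)
  function(t) dose_rate(model, t)
}

#' Total absorbed dose of a dose-rate model
#'
#' Integrates the dose-rate curve over all time. Closed form for the
#' exponential families; trapezoid areas over the linear segments plus the
#' analytic tail integral \eqn{\dot D(t_x)/\lambda_e} for the piecewise
#' model (the trapezoid-plus-exponential-tail rule of standard dosimetry
#' practice).
#'
#' @param model A dose-rate model.
#' @return Total absorbed dose in Gy.
#' @export
total_dose <- function(model) UseMethod("total_dose")

#' @rdname total_dose
#' @export
total_dose.biexp_dose_rate <- function(model) {
  model$r0 * (1 / model$lambda_e1 - 1 / model$lambda_e2)
}

#' @rdname total_dose
#' @export
total_dose.mono_dose_rate <- function(model) model$d0 / model$lambda_e

#' @rdname total_dose
#' @export
total_dose.piecewise_dose_rate <- function(model) {
  s <- model$samples
  head <- if (nrow(s) > 1L)
    sum(diff(s$t) * (s$ddot[-nrow(s)] + s$ddot[-1L]) / 2)
  else 0
  head + model$ddot_tx / model$lambda_e
}

#' @export
print.dose_rate_model <- function(x, ...) {
  cat(sprintf("<%s>\n", class(x)[1L]))
  flds <- x[!vapply(x, is.data.frame, logical(1L))]
  for (nm in names(flds)) cat(sprintf("  %s = %g\n", nm, flds[[nm]]))
  if (!is.null(x$samples))
    cat(sprintf("  %d linear-segment samples up to tx\n", nrow(x$samples)))
  cat(sprintf("  total dose = %.4g Gy\n", total_dose(x)))
  invisible(x)
}
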