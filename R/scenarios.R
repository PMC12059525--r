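#' Synthetic dose-rate scenarios
#'
#' Generates noiseless validation scenarios: measurement samples lying
#' exactly on a known truth curve, at the post-injection times typical of
#' clinical protocols (1, 4, 24, 72 h). Three kinds are provided:
#'
#' * `"biexponential"`: uptake-then-clearance curve; default truth
#'   `biexp_dose_rate(r0 = 2, lambda_e1 = 0.02, lambda_e2 = 0.5)` (effective
#'   clearance half-time ~35 h, uptake half-time ~1.4 h).
#' * `"monoexponential"`: single-phase decay; default truth
#'   `mono_dose_rate(d0 = 1, lambda_e = 0.05)` (half-time ~14 h).
#' * `"high_retention"`: tracer concentration plateaus, so the dose rate
#'   falls by physical decay alone. Default measurement table (1 h, 0.10),
#'   (4 h, 0.30), (24 h, 0.50), (72 h, 0.50) Gy/h — the non-decreasing final
#'   pair engages the zero-biological-clearance fallback, and the truth is
#'   the resulting piecewise model with a physical-decay-only tail.
#'
#' @param kind Scenario kind; see above.
#' @param truth Optional dose-rate model overriding the default truth (for
#'   `"high_retention"`, an optional data frame of samples with columns `t`,
#'   `ddot` whose final pair must be non-decreasing).
#' @param sample_times Measurement times, h (ignored for
#'   `"high_retention"`, whose samples define the truth).
#' @param params A [radiobio_params()] object; used by `"high_retention"`
#'   for the physical decay constant.
#' @return An object of class `"rpt_scenario"`: list with `kind`, `truth`
#'   (a dose-rate model), `sample_times`, and `samples`
#'   (a [dose_rate_samples()]).
#' @export
make_scenario <- function(kind = c("biexponential", "monoexponential",
                                   "high_retention"),
                          truth = NULL, sample_times = c(1, 4, 24, 72),
                          params = radiobio_params(10, trep = 1.5)) {
  kind <- match.arg(kind)
  stopifnot(inherits(params, "radiobio_params"))
  if (kind == "biexponential") {
    if (is.null(truth)) truth <- biexp_dose_rate(2, 0.02, 0.5)
    stopifnot(inherits(truth, "biexp_dose_rate"))
    samples <- dose_rate_samples(sample_times, dose_rate(truth, sample_times))
  } else if (kind == "monoexponential") {
    if (is.null(truth)) truth <- mono_dose_rate(1, 0.05)
    stopifnot(inherits(truth, "mono_dose_rate"))
    samples <- dose_rate_samples(sample_times, dose_rate(truth, sample_times))
  } else {
    samples <- if (is.null(truth))
      dose_rate_samples(c(1, 4, 24, 72), c(0.10, 0.30, 0.50, 0.50))
    else as_dose_rate_samples(truth)
    n <- nrow(samples)
    if (samples$ddot[n] < samples$ddot[n - 1L])
      stop("a high-retention scenario requires a non-decreasing final ",
           "sample pair (so the physical-decay-only tail rule engages)",
           call. = FALSE)
    truth <- build_piecewise(samples, k_last = 2L, params)
    sample_times <- samples$t
  }
  structure(list(kind = kind, truth = truth, sample_times = sample_times,
                 samples = samples),
            class = "rpt_scenario")
}

#' @export
print.rpt_scenario <- function(x, ...) {
  cat(sprintf("<rpt_scenario> kind = %s\n", x$kind))
  cat(sprintf("  samples at t = %s h\n",
              paste(signif(x$samples$t, 4), collapse = ", ")))
  cat(sprintf("  dose rates   = %s Gy/h\n",
              paste(signif(x$samples$ddot, 4), collapse = ", ")))
  invisible(x)
}

# reference EQD2 for a scenario: analytic engines for exponential truths,
# hybrid for piecewise truths
scenario_reference_eqdx <- function(scenario, params, X = 2,
                                    cfg = integration_config()) {
  engine <- if (inherits(scenario$truth, "piecewise_dose_rate"))
    "hybrid" else "analytic"
  compute_eqdx(scenario$truth, params, X = X, engine = engine, cfg = cfg)
}

#' Numerical-engine convergence as a function of stopping time
#'
#' Profiles the fully numerical engine's EQDX against its termination time:
#' EQDX is evaluated at `n_stops` stopping times between 72 h and `max_stop`
#' and compared with the reference value from the analytic engine
#' (exponential truths) or the hybrid engine (piecewise truths). Because the
#' double-integral and dose integrands are nonnegative, the profile is
#' monotone nondecreasing and bounded above by the reference: truncating the
#' extrapolation can only underestimate EQDX.
#'
#' If the recursion's overflow guard fires before `max_stop`, stopping times
#' beyond the last computable time get `NA`, the profile is flagged, and —
#' when the tolerance has not been reached by then — `min_stop_time_for_tol`
#' is `NA`: the numerical method fails before it converges.
#'
#' @param scenario An [make_scenario()] object.
#' @param params A [radiobio_params()] object.
#' @param cfg An [integration_config()] supplying the grid width `dt`.
#' @param n_stops Number of stopping times (default 1000).
#' @param max_stop Largest stopping time, h (default 2000; 200 for quick
#'   profiles).
#' @param tol Relative EQDX tolerance defining the minimum sufficient
#'   stopping time (default 0.02, i.e. 2%).
#' @param X Reference fraction size, Gy.
#' @return An object of class `"convergence_profile"`: list with
#'   `stop_times`, `eqdx_values`, `reference_eqdx`, `min_stop_time_for_tol`
#'   (`NA` if never reached), `tol`, `overflowed`, `overflow_time` and
#'   `kind`.
#' @export
convergence_profile <- function(scenario, params,
                                cfg = integration_config(),
                                n_stops = 1000, max_stop = 2000,
                                tol = 0.02, X = 2) {
  stopifnot(inherits(scenario, "rpt_scenario"),
            inherits(params, "radiobio_params"), max_stop > 72)
  ref <- scenario_reference_eqdx(scenario, params, X = X, cfg = cfg)
  t <- seq(0, max_stop, by = cfg$dt)
  gr <- numerical_grid(dose_rate_fun(scenario$truth), params, t)
  t_last <- gr$t[length(gr$t)]

  stops <- seq(72, max_stop, length.out = n_stops)
  idx <- findInterval(stops, gr$t)
  eq <- eqd2_from_DN(gr$D[idx], gr$N[idx], params$alpha_beta, X = X)
  eq[stops > t_last + cfg$dt] <- NA_real_

  rel_dev <- abs(eq - ref$EQDX) / ref$EQDX
  hit <- which(rel_dev < tol)
  min_stop <- if (length(hit)) stops[hit[1L]] else NA_real_

  structure(list(stop_times = stops, eqdx_values = eq,
                 reference_eqdx = ref$EQDX,
                 min_stop_time_for_tol = min_stop, tol = tol,
                 overflowed = gr$overflowed,
                 overflow_time = if (gr$overflowed) t_last else NA_real_,
                 kind = scenario$kind, X = X),
            class = "convergence_profile")
}

#' @export
print.convergence_profile <- function(x, ...) {
  cat(sprintf("<convergence_profile> %s scenario, EQD%g\n", x$kind, x$X))
  cat(sprintf("  reference EQD%g = %.4f Gy; %d stopping times in [%g, %g] h\n",
              x$X, x$reference_eqdx, length(x$stop_times),
              min(x$stop_times), max(x$stop_times)))
  if (is.na(x$min_stop_time_for_tol)) {
    cat(sprintf("  %.3g%% tolerance never reached", 100 * x$tol))
  } else {
    cat(sprintf("  %.3g%% tolerance reached from stop time %.4g h",
                100 * x$tol, x$min_stop_time_for_tol))
  }
  if (x$overflowed)
    cat(sprintf(" [overflow guard fired at %.4g h]", x$overflow_time))
  cat("\n")
  invisible(x)
}

#' Effect of omitting the final measurement on EQDX
#'
#' Re-creates the simplified-dosimetry comparison: the baseline is the
#' analytic EQDX from a biexponential fit to all four measurements; each
#' comparator then sees only the first three:
#'
#' * `analytic` — biexponential fit to 3 points, closed-form G;
#' * `hybrid` — piecewise linear-exponential model, hybrid G;
#' * `numerical` — the same piecewise model, trapezoid recursion truncated
#'   at `numerical_stop` (default 250 h, a stopping time chosen to stay just
#'   short of overflow at the fast repair half-time of 0.5 h).
#'
#' Reported differences are signed and relative:
#' `(comparator - baseline)/baseline`. For truth-generated samples the
#' numerical comparator's difference is necessarily negative (truncation
#' only ever discards nonnegative contributions).
#'
#' @param samples Exactly 4 dose-rate samples (a [dose_rate_samples()] or
#'   data frame with columns `t`, `ddot`).
#' @param params A [radiobio_params()] object (the study default repair
#'   half-time is 0.5 h).
#' @param numerical_stop Truncation time of the numerical comparator, h.
#' @param X Reference fraction size, Gy.
#' @param cfg An [integration_config()]; `dt` is used by the hybrid and
#'   numerical comparators.
#' @return An object of class `"omit_last_study"`: a data frame with one row
#'   per method (`baseline`, `analytic`, `hybrid`, `numerical`) and columns
#'   `method`, `n_points`, `D`, `G`, `EQDX`, `delta_rel`, `note`.
#' @export
omit_last_study <- function(samples, params, numerical_stop = 250, X = 2,
                            cfg = integration_config()) {
  stopifnot(inherits(params, "radiobio_params"))
  samples <- as_dose_rate_samples(samples)
  if (nrow(samples) != 4L)
    stop("the omission study requires exactly 4 measurements", call. = FALSE)
  s3 <- samples[1:3, , drop = FALSE]

  fit4 <- fit_biexponential(samples, params)
  if (!fit4$converged)
    stop("baseline 4-point biexponential fit failed: ", fit4$message,
         call. = FALSE)
  base <- compute_eqdx(fit4$model, params, X = X, engine = "analytic")

  row <- function(method, n_points, res, note = "") {
    if (is.null(res)) {
      data.frame(method = method, n_points = n_points, D = NA_real_,
                 G = NA_real_, EQDX = NA_real_, delta_rel = NA_real_,
                 note = note, stringsAsFactors = FALSE)
    } else {
      data.frame(method = method, n_points = n_points, D = res$D, G = res$G,
                 EQDX = res$EQDX,
                 delta_rel = (res$EQDX - base$EQDX) / base$EQDX,
                 note = note, stringsAsFactors = FALSE)
    }
  }

  fit3 <- fit_biexponential(s3, params)
  res_a <- if (fit3$converged)
    compute_eqdx(fit3$model, params, X = X, engine = "analytic") else NULL
  note_a <- if (fit3$converged) "" else paste("fit failed:", fit3$message)

  pw <- build_piecewise(s3, k_last = 2L, params)
  res_h <- compute_eqdx(pw, params, X = X, engine = "hybrid", cfg = cfg)

  cfg_num <- integration_config(dt = cfg$dt, stop_time = numerical_stop)
  res_n <- compute_eqdx(pw, params, X = X, engine = "numerical",
                        cfg = cfg_num)
  note_n <- if (res_n$overflowed)
    sprintf("overflow guard fired at %g h", res_n$stop_time_used) else ""

  out <- rbind(
    row("baseline", 4L, base),
    row("analytic", 3L, res_a, note_a),
    row("hybrid", 3L, res_h),
    row("numerical", 3L, res_n, note_n))
  out$delta_rel[out$method == "baseline"] <- 0
  structure(out, class = c("omit_last_study", "data.frame"),
            X = X, numerical_stop = numerical_stop)
}
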