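# shared fixtures: parameter sets and dose-rate models used across files

par_tumor <- function(trep = 1.5) radiobio_params(10, trep = trep)
par_organ <- function(trep = 1.5) radiobio_params(3, trep = trep)
par_norepair <- function() radiobio_params(10, trep = Inf)

biexp_default <- function() biexp_dose_rate(2, 0.02, 0.5)

# the worked piecewise fixture: tail anchored at 24 h, half-time 48 h
piecewise_fixture <- function() {
  piecewise_dose_rate(
    data.frame(t = c(0, 1, 4, 24, 72), ddot = c(0, 1, 0.8, 0.4, 0.2)),
    tx = 24, lambda_e = log(2) / 48)
}

# noiseless samples on a truth model at the clinical scan times
truth_samples <- function(model, times = c(1, 4, 24, 72)) {
  dose_rate_samples(times, dose_rate(model, times))
}

# simple quadrature of a dose-rate model, independent of total_dose()
quad_dose <- function(model, upper = 2000) {
  stats::integrate(function(t) dose_rate(model, t), 0, upper,
                   rel.tol = 1e-10, subdivisions = 500L)$value
}
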