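#!/usr/bin/env Rscript
# Wall-clock comparison of the three G-factor routes on the three built-in
# scenarios (hybrid vs fully numerical with the auto-stop convergence check
# vs brute-force double quadrature).  Informational only: timings depend on
# hardware and are asserted nowhere.
library(eqdx)

params <- radiobio_params(alpha_beta = 10, trep = 1.5)
cfg_auto <- integration_config(dt = 0.01, stop_time = 2000, auto_stop = TRUE)

time_ms <- function(expr, reps = 10) {
  expr <- substitute(expr)
  env <- parent.frame()
  t <- vapply(seq_len(reps), function(i)
    system.time(eval(expr, env))[["elapsed"]], numeric(1L))
  sprintf("%.1f +/- %.1f ms", 1000 * mean(t), 1000 * stats::sd(t))
}

for (kind in c("monoexponential", "biexponential", "high_retention")) {
  sc <- make_scenario(kind, params = params)
  pw <- if (inherits(sc$truth, "piecewise_dose_rate")) sc$truth
        else build_piecewise(sc$samples, 2L, params)
  cat(sprintf("\n== %s ==\n", kind))
  cat("  hybrid      :", time_ms(g_hybrid(pw, params)), "\n")
  cat("  numerical   :", time_ms(suppressWarnings(
    g_numerical(sc$truth, params, cfg_auto))), "\n")
  cat("  quadrature  :", time_ms(g_oracle(sc$truth, params), reps = 3), "\n")
}
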