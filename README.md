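# eqdx

Radiobiologically motivated dose metrics for radiopharmaceutical therapy
(RPT). Given sparse post-injection measurements of the mean absorbed dose
rate in an organ or tumor — typically 3–4 SPECT/CT time points after a
[¹⁷⁷Lu]Lu-DOTATATE administration — `eqdx` computes the Lea–Catcheside
dose-protraction factor *G*, the relative effectiveness RE, the biologically
effective dose BED, and the equieffective dose EQDX (EQD2 for X = 2 Gy)
under the linear-quadratic model with monoexponential sublethal-damage
repair.

## The model

During RPT, irradiation is continuous and concurrent with DNA damage
repair, so the quadratic kill term of the linear-quadratic model is scaled
by the protraction factor

```
G = ∫₀^∞ dt Ḋ(t) ∫₀^t dt' Ḋ(t') e^{−μ(t−t')}  /  (D²/2),      μ = ln2 / T_rep
```

which is the fraction of sublethal-lesion pairs that survive repair long
enough to interact (G ∈ (0, 1]; G = 1 means no repair). From G the usual
chain follows:

```
RE   = 1 + G·D/(α/β)
BED  = D·RE
EQDX = BED / (1 + X/(α/β))
```

The package provides four interchangeable engines for G:

| engine      | dose-rate model                        | method |
|-------------|----------------------------------------|--------|
| `analytic`  | biexponential `r₀(e^{−λe1 t} − e^{−λe2 t})` | closed form: `λe1 λe2 (λe1+λe2+μ) / [(λe1+λe2)(λe1+μ)(λe2+μ)]` |
| (mono limit)| monoexponential                        | `λe/(λe+μ)` |
| `hybrid`    | piecewise-linear head + exponential tail | trapezoid recursion to the tail anchor t_x, tail integrated analytically |
| `numerical` | any                                    | full trapezoid double-integration recursion to a stopping time |
| `oracle`    | any                                    | nested adaptive double quadrature (validation only) |

The fully numerical recursion carries a growing `e^{μt}` term: at
T_rep = 0.5 h it exceeds 10¹⁰⁰ after a week of extrapolation and leaves
double precision near 505 h. The engine guards this and reports a
structured overflow instead of crashing; the hybrid engine never
extrapolates numerically and is immune by construction.

## Worked example

Four scan-time dose rates (Gy/h) for one tumor region:

```r
library(eqdx)
params  <- radiobio_params(alpha_beta = 10, trep = 1.5)   # Gy, h
samples <- dose_rate_samples(t = c(1, 4, 24, 72),
                             ddot = c(0.747, 1.576, 1.238, 0.555))

fit <- fit_biexponential(samples, params)
fit
#> <biexp_fit>
#>   r0 = 1.90992 Gy/h, lambda_e1 = 0.0174561 1/h, lambda_e2 = 0.537375 1/h
#>   converged = TRUE (ok), residual norm = 0.03106 Gy/h, n = 4

compute_eqdx(fit$model, params, X = 2, engine = "analytic")
#> <eqdx_result> engine = analytic
#>   D = 105.8585 Gy, G = 0.035871, RE = 1.3797
#>   BED = 146.0559 Gy, EQD2 (alpha/beta = 10 Gy) = 121.7133 Gy

pw <- build_piecewise(samples, k_last = 2, params)
compute_eqdx(pw, params, X = 2, engine = "hybrid")
#> <eqdx_result> engine = hybrid
#>   D = 106.0665 Gy, G = 0.034011, RE = 1.3607
#>   BED = 144.3292 Gy, EQD2 (alpha/beta = 10 Gy) = 120.2743 Gy
```

Reading: the region receives ~106 Gy of absorbed dose; protracted delivery
lets most sublethal damage repair (G ≈ 0.035), so the dose is worth
~121 Gy in 2-Gy fractions rather than the ~530 Gy an acute exposure of the
same size would imply. The analytic (fitted-biexponential) and hybrid
(piecewise) routes agree to ~1%, the difference coming from the dose-rate
model, not the radiobiology.

## Command line

A thin wrapper over the same functions is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "eqdx.R", package = "eqdx"))')
Rscript $CLI simulate --out scenarios.csv
Rscript $CLI eqd2 --engine hybrid --trep 1.5 --out results.csv scenarios.csv
Rscript $CLI converge --engine numerical --stop-time 2000 --out profile.csv scenarios.csv
```

Subcommands: `fit`, `gfactor`, `eqd2`, `converge`, `simulate`,
`omit-study`. Input CSVs have header `region_id,time_h,dose_rate_gy_per_h`.

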