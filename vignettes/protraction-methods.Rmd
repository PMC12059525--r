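---
title: "Dose protraction, repair, and equieffective dose in RPT: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose protraction, repair, and equieffective dose in RPT: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eqdx)
```

## The problem

Radiopharmaceutical therapy (RPT) delivers dose continuously at an
exponentially falling rate over days to weeks, while sublethal DNA damage
is repaired on a timescale of hours. Dose–response work and organ
constraints are therefore phrased in equieffective doses (EQD2) rather
than absorbed dose, and converting one into the other requires the
Lea–Catcheside dose-protraction factor

$$G = \frac{\int_0^\infty \dot D(t) \int_0^t \dot D(t')\,
e^{-\mu(t-t')}\,dt'\,dt}{D^2/2}, \qquad \mu = \ln 2 / T_{rep},$$

the fraction of sublethal-lesion pairs formed close enough in time to
interact before repair removes one of them. `eqdx` computes $G$, and from
it $RE = 1 + GD/(\alpha/\beta)$, $BED = D\cdot RE$, and
$EQDX = BED/(1 + X/(\alpha/\beta))$.

### Assumptions

* **Linear-quadratic model with monoexponential repair.** The repair
  kernel is $\psi(t) = e^{-\mu t}$; multiphase or reciprocal repair kernels
  are out of scope (the analytic and hybrid routes below do not exist for
  them — the inner integral no longer separates).
* **Same $\alpha/\beta$ for the test and reference radiation.**
* **Local energy deposition.** Region-mean dose rates are modeled
  directly; cross-irradiation between regions is neglected, appropriate for
  short-range beta emitters such as ¹⁷⁷Lu.
* **Zero initial dose rate.** Activity builds up from nothing at
  injection, so $\dot D(0) = 0$; the biexponential model encodes this with
  equal and opposite amplitudes.
* **No repopulation.** Regrowth terms are independent of $G$ and RE and
  are omitted.

## The four engines

**Analytic.** For
$\dot D(t) = r_0(e^{-\lambda_{e1}t} - e^{-\lambda_{e2}t})$
(effective rates = biological clearance + physical decay;
$0 < \lambda_{e1} < \lambda_{e2}$),

$$G = \frac{\lambda_{e1}\lambda_{e2}(\lambda_{e1}+\lambda_{e2}+\mu)}
{(\lambda_{e1}+\lambda_{e2})(\lambda_{e1}+\mu)(\lambda_{e2}+\mu)},$$

independent of $r_0$, with $D = r_0(1/\lambda_{e1} - 1/\lambda_{e2})$.
The single-phase limit is $G = \lambda_e/(\lambda_e+\mu)$ (`g_mono()`).
`re_analytic_biexp()` evaluates the fully expanded RE in one expression;
tests verify it agrees with the assembled $1 + GD/(\alpha/\beta)$ route to
machine precision (a two-route identity, not a tautology: the code paths
share nothing).

**Fully numerical.** The dynamic-programming trapezoid recursion on a
uniform grid of width `dt`:
$M_m = M_{m-1} + \tfrac12(\dot D_m e^{\mu t_m} + \dot D_{m-1} e^{\mu t_{m-1}})\,dt$,
$N_m = N_{m-1} + \tfrac12(\dot D_m M_m e^{-\mu t_m} + \dot D_{m-1} M_{m-1} e^{-\mu t_{m-1}})\,dt$,
$G = N_{max}/(D^2/2)$. The recursion is kept faithful to the published
algorithm, growing exponential included: we deliberately do **not**
rescale it into the log domain, because its failure mode is part of what
the package characterises. A guard aborts when $\mu t > 700$
($e^{709.78}$ is the largest double) and reports a flagged partial result;
`on_overflow = "error"` turns this into a catchable condition class
carrying the partial breakdown. In the package the recursions are
implemented as vectorised cumulative sums, so one pass yields the result
at *every* stopping time on the grid — this is what makes the 1000-point
convergence profiles cheap.

**Hybrid.** For the piecewise linear-interpolation model with an
exponential tail from the anchor time $t_x$, the double integral is split
at $t_x$: the head is computed by the same recursions (interim values $N$
and $M$), the tail analytically:

$$G = \frac{2}{D^2}\Big[N + \frac{M\,\dot D(t_x)e^{-\mu t_x}}{\lambda_e+\mu}
+ \frac{\dot D^2(t_x)}{2\lambda_e(\lambda_e+\mu)}\Big].$$

$\mu t_x$ is bounded by the scan schedule ($t_x \le 72$ h), so overflow
cannot occur. With $t_x = 0$ the expression reduces *algebraically* to the
monoexponential formula, and the tests assert this to machine precision.

**Oracle.** Nested adaptive quadrature of the defining double integral
(`stats::integrate`, relative tolerance $10^{-9}$, absolute $10^{-12}$ per
nested integral), with the outer integral split at the model's knots and a
fixed set of tail break points, and the inner integral restricted to the
support of the repair kernel ($t - 60/\mu$ onward; older contributions are
below the absolute tolerance). The default horizon is
$\max(2000, 40/\lambda_{e,\text{slowest}})$ h, making the truncated tail
negligible. The oracle shares no code with the engines and is used only in
tests and the acceptance script.

## Parameters that matter

| parameter | units | default | notes |
|---|---|---|---|
| $\alpha/\beta$ | Gy | 10 (tumor-like), 3 (organ-like) | radiosensitivity ratio |
| $T_{rep}$ | h | study grid {0.5, 1.5, 3} | repair half-time; $\mu = \ln2/T_{rep}$; `Inf` = no repair |
| physical half-life | h | 159.528 (¹⁷⁷Lu, 6.647 d) | configurable per radionuclide |
| `dt` | h | 0.01 | recursion bin width; halving it moves results by < 0.01% (asserted) |
| `stop_time` | h | 2000 | numerical-engine termination / cap |
| auto-stop | — | start 72 h, step 10 h, tol 0.1% | published convergence protocol |
| $X$ | Gy | 2 | reference fraction size; ratios of EQDX are independent of it |

## The synthetic scenarios

`make_scenario()` generates noiseless measurements on a known truth curve
at the clinical scan times 1, 4, 24, 72 h:

* `biexponential`: $r_0 = 2$ Gy/h, $\lambda_{e1} = 0.02$/h,
  $\lambda_{e2} = 0.5$/h — effective clearance half-time ~35 h, uptake
  half-time ~1.4 h, total dose 96 Gy; a mid-range tumor-like curve.
* `monoexponential`: $\dot d_0 = 1$ Gy/h, $\lambda_e = 0.05$/h.
* `high_retention`: the fixture table (1 h, 0.10), (4 h, 0.30),
  (24 h, 0.50), (72 h, 0.50) Gy/h. The plateaued final pair engages the
  zero-biological-clearance rule, so the tail decays at the physical rate
  only — the slowest clinically plausible kinetics.

These defaults are package choices: they emulate the *shapes* of clinical
curves, not any specific patient. Consequences: passing tests demonstrate
the engines' mutual consistency, convergence ordering, and failure modes
on representative kinetics; they do not certify accuracy on real data,
where measurement noise, model misspecification (curves that are not
truly biexponential), and partial-volume effects dominate. For the same
reason the published per-patient omission-study percentages and exact
minimum stopping times are not reproduced numerically — only their
mechanisms and ordering are (our high-retention scenario happens to need
~885 h for 2% accuracy at $T_{rep}=1.5$ h, closely matching the ~890 h
scale reported for such kinetics, but this is a qualitative anchor, not a
target).

**Omission-study truth.** The four-to-three-scans driver
(`omit_last_study()`) defaults in the acceptance analysis to a truth of
$(r_0 = 2, \lambda_{e1} = 0.02, \lambda_{e2} = 2.0)$: fast uptake (peak
~2.3 h, before the second scan) with slow clearance. This was chosen on
kinetic grounds: clinical organ and tumor curves peak near the first scan,
and a truth that peaks *after* the 4 h scan (as the default biexponential
scenario does, at 6.7 h) makes a three-point piecewise tail anchor on the
rising limb, a pathology the clinical study design never encounters. With
the fast-uptake truth the expected ordering emerges: the truncated
numerical comparator is strictly negative and larger in magnitude than
the hybrid error, while the three-point analytic fit recovers the
baseline exactly (three noiseless points plus the zero-origin constraint
identify the three-parameter model).

## Numerical choices and degenerate inputs

* **Grids.** The hybrid head grid is the union of a uniform `dt` mesh and
  the sample knots, so kinks always sit on grid points; the numerical
  engine's uniform grid starts at $t = 0$ with $M_0 = N_0 = 0$.
* **Overflow guard at $\mu t > 700$.** At $T_{rep} = 0.5$ h the interim
  term reaches $10^{100}$ after 7 days ($\log_{10} e^{\mu\cdot168} \approx
  101.1$) and leaves double range at $t \approx 505$ h.
* **Monotone convergence.** All integrands are nonnegative, so the
  numerical engine's $N$, $D$, and hence EQD2 are nondecreasing in
  stopping time and bounded by the analytic value — up to $O(dt^2)$
  trapezoid overshoot (measured: ~$3\times10^{-7}$ relative at
  `dt = 0.01`), which the tests' bounds accommodate explicitly.
* **Fitting.** Unweighted nonlinear least squares (the data carry no
  stated uncertainty model) via Levenberg–Marquardt with box bounds. The
  gap parameterisation $\lambda_{e2} = \lambda_{e1} + \delta$, $\delta >
  0$, removes label-switching structurally, and $\lambda_{e1}$ is bounded
  below by the physical decay constant. Multi-start uses a fixed 8-row
  multiplicative factor grid around a log-slope-derived initial guess
  rather than seeded random perturbations — equally deterministic, and
  repeated fits are bit-identical without touching the RNG state. The
  degenerate equal-rates model is rejected (relative gap $\ge 10^{-6}$).
* **Piecewise head on $[0, t_1]$.** A linear segment from $(0, 0)$ to the
  first sample, consistent with the zero-initial-dose-rate assumption.
  This is a genuine modeling choice (measurement-driven workflows differ
  here); its error is proportional to the first scan time and dominates
  the piecewise dose error for monoexponential truths (asserted as a
  densification property in the tests).
* **Tail rate fallback.** If the log-slope of the final samples implies
  negative biological clearance (non-decaying tail, as with high tumor
  retention or quantitation noise), the tail decays at the physical rate
  only. Zero dose rates among the tail samples are an error, not clamped.
* **Single-sample piecewise model.** Accepted as the degenerate pure
  exponential anchored at that sample, with a physical-decay-only tail
  (no clearance information exists); this keeps the hybrid engine total
  on the one-scan-per-cycle workflow.
* **Multi-cycle treatment.** Reported as a per-cycle sum assuming
  identical kinetics and complete inter-cycle repair; no interaction term.

## Problem sizes

The test suite and acceptance analysis run the numerical engine at
`dt = 0.01` h over up to 2000 h (200k grid points, vectorised), profile
1000 stopping times per scenario in one pass, evaluate the oracle over a
$3\times3\times3$ grid of $(\lambda_{e1}, \lambda_{e2}, T_{rep})$ for both
the analytic and hybrid engines, and fit 200 noise replicates at 1%
multiplicative noise. A 2000 h numerical run at $T_{rep} \le 1.5$ h does
not exist — $e^{\mu t}$ overflows first (at ~1514 h for 1.5 h) — so the
0.1%-at-2000 h convergence checks use $T_{rep} = 3$ h, the one value of
the study grid for which the published recursion completes; this is a
property of that algorithm, and precisely the limitation the hybrid
method removes.

## Known limitations

* Monoexponential repair only; for reciprocal-form kernels none of the
  fast routes apply and only symbolic/numeric double integration remains.
* Region-mean dose rates; no voxel maps, no DICOM ingestion.
* The linear-quadratic framework itself is extrapolated from EBRT
  experience; $\alpha/\beta$ and $T_{rep}$ for RPT are uncertain, and all
  outputs should be read conditional on those parameters.
* The baseline numerical engine is intentionally faithful to its published
  form, including its overflow failure; it should be used for
  cross-validation, not production dosimetry.

## Session info

```{r}
sessionInfo()
```
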