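---
title: "Models and methods behind cocoflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cocoflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cocoflux)
```

cocoflux models crossflow microfiltration of green coconut water on a
silicon-carbide membrane and carries the optimized operating point through
to a screening-level economic analysis. This vignette explains each model,
its assumptions, the tunable parameters, and the numerical and design
choices made where more than one convention was defensible.

## The designed experiment and its data model

The experiment is a two-factor face-centered central composite design:
transmembrane pressure 50–200 kPa and feed temperature 20–40 °C, each at
three levels (coded −1, 0, +1 with the axial points on the cube faces, so no
level leaves the operating window). The 9 unique conditions are run in
triplicate off-center and in quintuplicate at the center — 13 runs, 29
samples. Responses are permeate flux (L h⁻¹ m⁻²) and the fouling index (%),
the permeance-based percentage loss of hydraulic permeability.

`coconut_design()` ships the experiment table. The five center samples are
individual measurements; for the eight non-center conditions only the
condition mean and standard deviation were recorded, so the fixture stores
the mean with replicate multiplicity 3. This choice is lossless for model
fitting: least squares only sees per-condition sums, so every fitted
coefficient equals what the raw replicates would give (the replicate-weight
identity is asserted in the test suite). What it cannot reproduce is any
statistic that depends on within-condition spread at non-center points —
sample-level error metrics computed from this fixture are therefore
approximations, and the cross-validation numbers quoted below should be
read with that caveat.

Coded units are the canonical internal representation; actual units appear
only at the I/O boundary (`code_level()` / `decode_level()` are exact
inverses).

## The quadratic response surface

`fit_rsm()` implements the reference recipe: fit the full two-factor
quadratic on all 29 samples by OLS, drop every non-intercept term whose
p-value exceeds α = 0.05, and refit. For flux this removes the pressure
linear term; for the fouling index, the temperature linear and pressure
quadratic terms. Ties at exactly p = α are retained (dropping requires
strict inequality). Because the FCD's columns are mutually orthogonal, the
intercept (660.59 for flux) is identical in the full and pruned fits.

Predictions carry standard errors from the reduced-model coefficient
covariance. One reproduction note: the recomputed prediction at the
(−1, −1) corner is 347.73, while the tabulated source value is 347.53; every
other design-point prediction agrees to ±0.01, so the package treats 347.73
as correct and the tabulated figure as a typo. The printed ± values
accompanying the source predictions do not coincide with OLS prediction
standard errors under any weighting we could reconstruct, so they are not
asserted.

`anova_rsm()` decomposes the total sum of squares into regression and
residual, and the residual into lack-of-fit and pure error (estimable here
because the design is replicated). F_cal is the regression/residual
mean-square ratio, compared against the F quantile at α with
(df_regression, df_residual).

`optimize_surface()` is deterministic: the stationary point solves the
2×2 zero-gradient system; each box edge is a one-variable quadratic with a
closed-form vertex; the best feasible candidate among interior point, edge
vertices and corners wins. The reduced flux surface has an interior maximum
at coded (0.0248, 0.2832) ≈ 126.9 kPa / 32.8 °C, value ≈ 671.9 L h⁻¹ m⁻²;
the fouling surface is minimized on the low-pressure edge.

## The neural surrogate

The surrogate is the classical compact architecture for two-input process
mapping: 2 inputs → 5 tansig hidden neurons → 2 purelin outputs, with all
variables min–max scaled to [−1, 1]. (One source rendering of the tansig
formula is garbled; the implementation uses the standard
`2/(1 + exp(−2n)) − 1`.) Training minimizes

    perf = (1 − λ)·MSE + λ·MSW,   λ = 0.10 by default,

where MSW is the mean squared weight/bias — the usual meaning of a
"regularization parameter" in this setting. λ is configurable via
`ann_config()`.

Levenberg–Marquardt treats the regularized objective as an augmented
least-squares problem and solves (JᵀJ + μI)δ = −Jᵀr with analytic
Jacobians; μ starts at 10⁻³, shrinks ×10 on an accepted step, grows ×10 on
a rejected one, and training stops at μ > 10¹⁰, 1000 epochs, or 6
consecutive validation failures (the weights at the best validation error
are kept). Weights initialize uniformly in [−0.5, 0.5] from the run seed.

The 70/15/15 split is applied at the sample level by largest-remainder
apportionment with remainder ties resolved test-first, which yields the
20/4/5 split at n = 29. Scalers are fitted on all samples by default
(`scale_on = "train"` restricts them); the original training setup did not
state which convention was used, and for this design the difference is
immaterial because the extreme levels always appear in training.

Model selection is best-of-restarts on validation MSE (`select_best_mlp()`,
20 restarts in the reference preset). The surrogate's published point
predictions depend on an unrecorded random initialization, so they are
treated as references: tests assert a stochastic envelope (center flux
within ±5 % of 659.19; all-subset pooled R² ≥ 0.95 on scaled targets for
the best of 20 restarts) rather than exact values.

## The genetic algorithm

`run_ga()` minimizes over the pressure–temperature box with the reference
configuration: population 120, 50 generations, 5 % elites, stall limit 8.
The exact variation operators of the original toolbox run are not fully
specified, so documented, testable equivalents are used: size-2 tournament
selection, BLX-0.5 blend crossover on 80 % of pairings, and Gaussian
mutation whose step decays linearly over the generations (floor 10⁻⁴ of
the span), with offspring clamped to bounds. Stall counts generations with
absolute best-fitness improvement below 10⁻⁶. Flux maximization uses
fitness = −J_p, so converged best-fitness values are negative; fouling
minimization uses the prediction directly. The GA is validated against the
closed-form optimum of the quadratic surface (agreement within 1 kPa /
0.2 °C) rather than against published GA outputs, which inherit the
unreproducible network.

## Cross-validated model comparison

`fit_metrics()` provides the error suite; two printed-form quirks are
resolved on the side of standard definitions, each with a `literal` escape
hatch: the R²/Q² denominator uses Σ(X_A − X_M)² (the stated interpretation
of negative Q² — "worse than predicting the mean" — requires it), and
RMSE_CV takes a true root mean square.

`loco_cv()` holds out all replicates of one condition per fold. The source
describes "13 unique conditions", but only 9 are geometrically distinct;
the default uses 9 true condition folds (no replicate leakage), and
`folds = "run"` reproduces the 13-row reading. On the fixture the pruned
quadratic attains Q² ≈ 0.36 (flux) and ≈ 0.79 (fouling), while the
surrogate's flux Q² is negative — the qualitative ordering the comparison
is designed to expose. Exact published Q² values are not reproducible from
mean-filled replicates and an unseeded network, so tests assert sign and
ordering, not digits.

## Fouling analysis

The resistance-in-series identities map the clean-water permeance
staircase (clean, post-run, post-physical-clean, post-chemical-clean) to
membrane, polarization, reversible and irreversible resistances; the four
components telescope exactly to 1/(µ_w·Lp₁), a property the tests check on
1000 random staircases. Water viscosity defaults to 1.0 mPa s; fluxes are
converted to m s⁻¹ and pressures to Pa at the boundary. The fouling index
(permeance-based) is deliberately distinct from `flux_decline_pct()`, the
in-run relative flux decline (≈91 % in the concentration-mode run), which
includes fully reversible polarization.

Hermia's four constant-pressure blocking laws are fitted by OLS on the
linearizing transform (ln J, J^(−1/2), J^(−1), J^(−2) against time) and
ranked by the linearized R² — the conventional selection criterion for
these semi-empirical models. One printed linear form omits the time factor
in the standard law; the implementation restores it. A `burn_in` argument
(default 0 h) can exclude the initial polarization-dominated decline. When
the top two R² differ by less than 0.01 the ranking is flagged as a mixed
regime, which is the realistic outcome for 2-hour runs where blocking and
cake formation overlap; the package reports rankings and does not encode a
canonical winning mechanism.

## Techno-economic model

The cash-flow model is a transparent screening layer over fixture cost
inputs: CAPEX US$959,000 and OPEX US$1,178,000/yr (itemized in
`baseline_costs()`), revenue from 25,742.1 cases of water at US$16.80 and
103,226.25 cases of pulp at US$11.20. (The water case count is implied by
the reported water revenue at the stated price; the originally printed
count is off by a factor of ten and is preserved as a provenance note.)
Timing: CAPEX spread over the 30 construction months in 12-month slices
ending at year 0; operations start after the 4-month start-up, so the
first operating year carries 8/12 of a full year; revenue and OPEX inflate
at 4 %/yr; discounting at 13 % from year 0. Taxes, depreciation and
working-capital release are not modelled — the published NPV/IRR/payback
come from a proprietary simulator with unpublished schedules, so this
package asserts the reproducible identities (demand, prices, revenue) and
self-consistency (NPV at IRR equals zero, NPV monotone decreasing in the
discount rate and increasing in the price multiplier, a loss-making −20 %
price scenario) instead of those figures. The gross margin recomputes to
25.85 % from the rounded OPEX total.

## Synthetic data

The generators exist so that every pipeline stage is testable without any
external data, and their defaults are fixed at the magnitudes of the real
process:

* `gen_fcd_dataset()` draws replicate responses from known quadratic
  coefficients (defaults: the full-model fit of the experiment table) with
  additive Gaussian noise (flux SD 15, fouling SD 1 — the scale of the
  observed replicate SDs). Additive noise matches how replicate spread is
  reported. Zero-noise generation recovers the coefficients exactly; at
  SD 15 the 2-standard-error coverage of fitted coefficients is ≈95 %.
* `gen_flux_series()` multiplies a closed-form blocking-law decay by
  lognormal noise (CV 2 % by default), keeping fluxes positive, with the
  first point pinned to J₀. Defaults: J₀ = 600 L h⁻¹ m⁻², 2-minute
  sampling for 2 h, and a rate constant that halves the flux over the run.
  Under these conditions mechanism selection recovers the generating law
  in ≥ 90 % of 200 seeded series per law.
* `gen_permeances()` inverts the telescoping identity to build a permeance
  staircase with exactly requested resistance shares.

What the generators do not emulate: drift within a run (the FCD noise is
i.i.d.), temperature-dependent viscosity, correlated replicate errors, or
mixed blocking regimes. Passing the recovery tests therefore demonstrates
correctness of the estimators under their own assumptions, not robustness
to every feature of real plant data.

## Problem sizes and runtime choices

The simulation studies are sized for tight feedback during development:
200 seeds per blocking law for mechanism recovery, 200 seeds for
coefficient-coverage calibration, 21 seeds for GA accuracy medians, 20
restarts for surrogate selection. These sizes give binomial standard
errors comfortably below the margins being asserted (e.g. a true 95 %
recovery rate is ≥ 90 % in a 200-draw sample with probability > 0.99).

## Known limitations

* Non-center replicate values are mean-filled; sample-level error metrics
  and Table-level Q² digits are approximations by construction.
* The surrogate's published predictions are initialization-dependent and
  are bounded, not matched.
* The cash-flow model omits tax/depreciation schedules; its NPV/IRR are
  internally consistent screening values only.
* The Hermia module fits each law independently; combined/serial blocking
  models are out of scope, as are the physical decompositions of the rate
  constants, which are not identifiable from flux data alone.
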