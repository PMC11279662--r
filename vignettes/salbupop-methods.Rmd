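---
title: "Population pharmacokinetics of inhaled salbutamol: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population pharmacokinetics of inhaled salbutamol: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(salbupop)
```

salbupop implements a complete population-pharmacokinetic (popPK) workflow for
a single 600 ug inhaled dose of salbutamol: a virtual-cohort simulator, a
noncompartmental analysis (NCA) stage, maximum-likelihood estimation of a
nonlinear mixed-effects model by stochastic-approximation EM (SAEM), stepwise
covariate selection, and the standard model-evaluation surfaces (weighted
residuals, NPDE, VPC, information criteria). This vignette documents the
models, the tunable parameters, the numerical choices, and the limits of what
the package's own simulated data can demonstrate.

## The structural model

The default disposition model is a two-compartment model with first-order
absorption from a depot (no lag) and linear elimination. In the clearance
parameterization the parameters are the absorption rate constant `ka` (1/h),
apparent clearance `Cl` (L/h), central volume `V1` (L), intercompartmental
clearance `Q` (L/h) and peripheral volume `V2` (L); bioavailability is folded
into the apparent parameters (the `Cl/F` convention), since the analyses this
package reproduces never separate an F. Internally everything is expressed in
ug, L and h, so concentrations are ug/L; files declaring ug/mL are converted
on import.

`predict_concentration()` evaluates the closed-form poly-exponential solution
(micro constants `k10 = Cl/V1`, `k12 = Q/V1`, `k21 = Q/V2`; disposition
eigenvalues from the characteristic polynomial; first-order input by
convolution). `predict_concentration_ode()` integrates the equivalent
mass-balance ODE system with `deSolve` and carries the cumulative eliminated
amount, so total mass is conserved to integrator tolerance; the test suite
holds the two routes to a relative agreement of 1e-8 wherever concentrations
are numerically nonzero. A registry (`model_registry()`) exposes 1-, 2- and
3-compartment variants with optional absorption lag for model-selection
experiments.

Two removable singularities are handled explicitly: when `ka` collides with a
disposition eigenvalue (relative gap below 1e-9) `ka` is nudged by one part in
1e9, and coincident disposition eigenvalues are split the same way.

## The statistical model

Individual parameters are log-normal around covariate-adjusted typical values:
on the log scale, `phi_i = X_i psi + eta_i` with `eta_i ~ N(0, Omega)`.
`Omega` is diagonal except for declared pairs (by default `ka`-`Q`).
Continuous covariates act as powers of the covariate/reference ratio,
categorical ones as `exp(beta)` shifts off a reference level. Observations
follow the combined error model on the standard-deviation scale,

    y = f + (a + b f) * eps,   eps ~ N(0, 1),

with `a` in ug/L and `b` unitless (defaults in the reference simulator:
`a = 0.05`, `b = 0.10`).

## The virtual cohort and the simulator

`default_virtual_cohort()` is a deterministic 32-subject table reproducing the
study-design margins: 18 male / 14 female; 12 American Indian or Alaskan
Native and 20 East Asian subjects (10 Japanese, 10 Chinese); ages from the
design set {5, 10, 20, 30, 65} years with median 20.0; BMI spanning the
normal, overweight and obese bands. The anthropometric values are package
constants chosen to approximate the published medians — the appendix with the
individual characteristics is not public, so these are documented
approximations, not reproductions. `sample_cohort()` draws arbitrary-size
cohorts from the same composition rules with per-subject random streams
(fixed offsets from the master seed), so enlarging a cohort never reshuffles
earlier subjects.

`simulate_dataset()` produces NONMEM-style records (`ID, TIME, AMT, DV, EVID,
MDV`) on the 14-point 0-12 h clinical schedule with a single 600 ug depot
dose at t = 0 (the three successive 200 ug inhalations are merged into one
bolus; their spacing is unreported and is minutes at most). Negative simulated
concentrations — possible under the additive error component — are truncated
at zero and flagged in the `TRUNC` column, because plasma concentrations are
physical quantities. The same truncation rule is applied to the replicate
simulations used by the NPDE and VPC machinery, so the diagnostics compare
like with like; prediction-distribution-error ranks use a midrank rule for the
resulting ties at zero.

The reference generating model (`default_pop_model()`) uses the published
population estimates with two substitutions discussed below, the published IIV
standard deviations for `ka`, `Cl`, `Q`, `V2`, the published `ka`-`Q`
correlation 0.89, and combined error `a = 0.05`, `b = 0.10`.

### Covariate-effect constants

The source analysis reports *which* covariate-parameter relationships exist
and their qualitative direction, but never prints coefficient values. The
simulator therefore uses documented package constants
(`default_covariate_effects()`), chosen once, at design time, to reproduce the
qualitative stratified orderings of the study population: higher clearance,
absorption rate and near-peak concentrations in the young stratum (5-22 y);
reduced `Cl`, `Q` and `V2` above 75 kg; reduced `ka` and roughly halved `Cl`
in females; lower `Cl` in East Asian subjects. An age effect on `ka` is
included even though the published covariate model attaches gender (not age)
to `ka`: the published data exploration reports visibly increased absorption
and higher concentrations in the young, and without an age-on-`ka` term the
young stratum cannot show higher near-peak concentrations, because its higher
clearance works in the opposite direction. These constants describe the
simulator only; they are not claims about the source study's coefficients.

## Identifiability under the published values: what to expect

The published estimates make the reference model *structurally degenerate*,
and this drives most of the package's design choices:

* The published central volume is 2e-11 L with an undefined ("infinitely
  large") standard error — a boundary artifact. The simulator substitutes
  `V1 = 1 L`, omits IIV on `V1` (its published IIV, 10.09 on the log-SD
  scale, is flagged the same way), and the default fit specification holds
  `V1` fixed at 1 L. With `V1` free the model is unidentifiable.
* With `V1 = 1 L`, the micro constants are `k10 = 24.3/h`, `k12 = 10.6/h`,
  `k21 = 1604/h`; the fast disposition eigenvalue is about 1615/h (half-life
  1.5 s), invisible at the first sample (0.08 h = 4.8 min). The observable
  profile is numerically a two-exponential with rates 3.71/h and 24.2/h and
  amplitude +-108 ug/L; the amplitude of the fast phase is 0.009 ug/L. `Q`
  and `V2` perturb the observable profile at below the 1% level while the
  residual error is 10%, so they are *practically unidentified*: their
  estimates wander in a flat likelihood valley, their linearization standard
  errors are typically undefined (the information matrix is singular in those
  directions, mirroring the published NaN standard errors), and the per-subject
  random effect on `Q` is unobservable — which also leaves the `ka`-`Q`
  correlation without data information. The identified quantities are `ka`,
  `Cl`, their IIVs, and the residual parameters.
* First-order absorption models are flip-flop ambiguous: exchanging the
  fast/slow rate labels (with compensating disposition parameters)
  reproduces the sampled profile at statistically indistinguishable
  likelihood. `fit_saem()` therefore runs SAEM from both label assignments
  produced by curve-stripping the median profile, and keeps the
  absorption-limited (terminal-slope) labeling — the standard convention for
  inhaled depot formulations, and the labeling of the published estimates
  (`ka = 3.71/h` far below `k10`) — unless a rival mode is decisively better
  (-2LL margin of 10, a Jeffreys-scale "decisive" factor).

## SAEM implementation

`fit_saem()` runs a two-phase SAEM: 500 exploratory iterations at constant
step size (with simulated-annealing lower bounds that keep variance
components from collapsing by more than 5% per iteration) and 200 smoothing
iterations with step size `1/k^0.7` (both counts, and the exponent, are
`saem_settings()` arguments). Each iteration runs, per subject, one
prior-independence Metropolis kernel and two adaptive componentwise
random-walk sweeps, vectorized across subjects sharing a sampling grid.
Sufficient statistics for the fixed effects (GLS update, exact for the
exponential family) and for `Omega` (second moments projected onto the
declared diagonal-plus-pairs structure) are updated by stochastic
approximation; the combined-error pair `(a, b)`, which is not exponential
family, is updated by a damped Nelder-Mead M-step. Estimated correlations are
capped at |rho| = 0.95: nearer the boundary the inverse covariance becomes
ill-conditioned and destabilizes the GLS update. IIV standard deviations are
floored at 1e-6 with a boundary flag to keep the conditional chains proper.

Starting values are data-driven: clearance from dose over the median-profile
AUC (trapezoids plus a clean-tail extrapolation that ignores samples below
0.5% of the median Cmax, where the additive noise floor dominates), `ka`
candidates from the terminal slope and the stripped fast rate, and remaining
parameters from a coarse log-grid fit to the median profile. Covariate
coefficients start at 0 with continuous references at the in-data median.

Conditional modes (EBEs) are found by per-subject numerical optimization;
conditional draws are retained from the tail of the smoothing phase (and
`conditional_mcmc()` samples them directly for a fixed model). The marginal
-2LL uses per-subject importance sampling from a multivariate t (df = 5)
proposal centered at the EBE, with an eigen-floored scale matrix;
`marginal_loglik()` provides the same computation for a fixed `pop_model`
without any fitting, collapsing to the closed-form residual likelihood when no
random effects are present. Standard errors come from a central-difference
Hessian of the FOCE-style linearized marginal likelihood in transformed
coordinates (log fixed effects and variances, atanh correlations), with
undefined entries reported as `NA` rather than failing.

## Covariate selection and confirmation

`screen_covariates()` tests each random effect against each candidate
covariate on per-subject conditional draws (Pearson correlation for
continuous, one-way ANOVA for categorical covariates), running the test per
draw (10 by default) and reporting the median p-value — less shrinkage-biased
than testing the conditional modes. `stepwise_select()` then alternates a
forward phase (add the smallest-p candidate below `alpha_add = 0.05`, keep it
only if the refit lowers BICc) and a backward phase (remove the highest
Wald-p retained effect above `alpha_remove = 0.05`, keep the removal only if
BICc drops), iterating to a fixed point with bounded revisits; refits
warm-start at the incumbent estimates. BMI is not a default candidate because
it is a deterministic function of weight and height. `confirm_tests()` reports
Wald tests per coefficient, Shapiro-Wilk normality per random effect, and a
signed-rank symmetry test on the individual weighted residuals.

`information_criteria()` implements `AIC = -2LL + 2p`, `BIC = -2LL + p log N`
and the corrected `BICc = -2LL + p_R log N + p_F log n_obs`, where `p_R`
counts parameters attached to subject-level structure and `p_F` the
residual-error parameters. Structure-selection experiments compare *base*
statistical models (diagonal `Omega`, no covariates) across 1-, 2- and
3-compartment candidates; the `ka`-`Q` correlation enters the model only
after the structure is chosen, which is also the order of operations in the
source workflow.

## Diagnostics

`residual_table()` reports IPRED (conditional-mode predictions), PRED
(simulation-based population means), IWRES, simulation-decorrelated PWRES
(symmetric matrix square root, so the decorrelation is invariant to
observation ordering), and NPDE with the half-count continuity correction,
clamped to `(1/(2K), 1 - 1/(2K))`. `outlier_proportion()` measures the
fraction of observations outside `IPRED +- z * (a + b IPRED)`; note that
conditional-mode predictions absorb part of the residual noise, so with many
random effects per subject the empirical fraction runs below nominal
(classical EBE optimism) — the calibration tests use a single-random-effect
fixture where the effect is negligible. `vpc()` bins by nominal time (the
designs are fixed-grid; bins under 3 observations merge with a neighbor),
and compares observed 10th/50th/90th percentiles with percentile-of-percentile
prediction intervals from replicate simulations. `stratified_summary()`
applies geometric mean / geometric SD summaries within the default strata
(age 5-22 vs 23-65 y, weight up to / above 75 kg, gender, race).

## Problem sizes and what the tests show

The packaged experiments run at the study's own scale — 32 subjects, 14
samples each — with replicate suites (covariate-selection operating
characteristics, standard-error calibration) at 20-50 seeded replicates of
reduced fits, and distributional nulls (NPDE, VPC coverage) at 400-500
simulation replicates. Passing them shows the machinery is internally
consistent under the stated generating mechanism: log-normal IIV,
combined-1 error, a fixed sampling grid, single dose, no BQL censoring rule
beyond truncation at zero, and covariates drawn from the documented
composition rules. It does not show that real inhaled-salbutamol data meet
those assumptions, and the dataset-bound statistics of the source study
(its -2LL, BICc, outlier percentages and NCA tables) are not reproducible
without its non-distributable datasets.

## Known limitations

* `Q`, `V2` and the `ka`-`Q` correlation are not data-identified under the
  published parameter regime (see above); the package reports them with
  undefined standard errors rather than hiding them.
* Truncation at zero biases the additive error component downward on designs
  that sample far into the noise floor (the reference design does); this is
  visible as a modestly inflated NPDE variance at the reference conditions.
* Single-dose, single-analyte, fixed-grid designs only; no inter-occasion
  variability, no BQL likelihood, no Michaelis-Menten elimination (rejected
  by the source model selection; only linear elimination is implemented).
* The stochastic-approximation alternative for the Fisher information is not
  implemented; `standard_errors()` offers linearization only.
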