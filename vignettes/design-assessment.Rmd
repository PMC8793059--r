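---
title: "Assessing experimental designs for time-lapse imaging of early biofilms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing experimental designs for time-lapse imaging of early biofilms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biofilmdesign)
```

## The statistical problem

A time-lapse confocal study of early biofilm colonization produces, for
each frame, a single thresholded fluorescence area — a surrogate for
attached biomass. These measurements are nested: frames within a field of
view (FOV), FOVs within an independent experiment. The three levels
contribute very different amounts of variability, and consecutive frames of
one FOV are strongly serially correlated, so the *effective* information in
a fast frame rate is small. The question this package answers is: given the
variance at each level, how many experiments, FOVs per experiment, and
frames per hour are needed to estimate a mean response — mean log10 area of
untreated biofilm, or the mean log reduction (LR) under an antimicrobial
treatment — with a prescribed precision?

## Model and estimation

All analysis happens on the log10 area scale. `fit_components()` fits, via
REML in `lme4`,

log10(area) = fixed part + b_exp + b_fov(exp) + e,

with a linear time covariate in the fixed part by default (the per-hour
model). Phase-pooled analyses can pass additional covariates — log inoculum,
period indicators, and their interactions with time — through the `fixed`
formula. Random intercepts for experiment and FOV-within-experiment and the
residual give `Var_exp`, `Var_FOV` and `Var_time`. Negative REML solutions
are truncated at zero. A method-of-moments expected-mean-square estimator
(`method = "moments"`) is provided for perfectly balanced designs, where it
coincides with REML; it is mainly a cross-check.

Serial correlation is handled by the two-stage fit-then-inflate approach
classically used for serially correlated regression residuals: the lag-1
coefficient is pooled across FOV series,

r = sum over series of sum_{t>=2} res_t res_{t-1} / sum over all residuals res_t^2,

with lagged products never crossing a series boundary and the denominator
running over all t (including the first frame of every series). The time
variance is then inflated by `c = (1 + r)/(1 − r)` wherever a design is
evaluated. We deliberately do not fit a joint AR(1)-within-LMM likelihood;
the two-stage approach is the procedure the design formulas assume.

### The design formulas

For `n_exp` experiments, `n_fov` FOVs, `n_time` frames per analysis window:

SEM² = Var_exp/n_exp + Var_FOV/(n_exp n_fov) + Var_time·c/(n_exp n_fov n_time),

Repeatability SD = sqrt(Var_exp + Var_FOV + Var_time·c),

MOE = t(0.95, n_exp − 1) × SEM (one-sided).

A packaged profile table (`phase_profiles()`) provides per-phase
repeatability SDs, variance proportions, `r` and `c` for lag
(0–2 h), early-exponential (2–4 h) and late-exponential (4–8 h) growth of a
reference *S. aureus* system. An important convention, adopted after
checking it numerically against the published worked example: the profile's
repeatability SD squared equals the **uninflated** sum
`Var_exp + Var_FOV + Var_time`, and the inflation factor is applied only
inside the SEM/repeatability formulas at evaluation time. The alternative
reading (SD already inflated) cannot reproduce the worked SEM of 0.191 for
the (2, 3, 20) early-phase design, so it was rejected. The discrepancy
between the two readings is documented rather than resolved; all package
computations use the evaluation-time convention consistently.

### Degrees of freedom, and `n_exp = 1`

Only the number of experiments contributes degrees of freedom
(`df = n_exp − 1`): experiments are the unit of independent replication.
For a single experiment the convention `df = 0.5` is adopted verbatim to
give an approximate (and intentionally enormous, t ≈ 41) multiplier;
`stats::qt()` handles fractional df exactly, so no custom quantile inversion
is needed. The confidence level is a knob (`conf`, default one-sided 0.95).

## Log reductions and treatment designs

`compute_lr()` forms, per treated FOV and frame,
`LR = log10(mean control area) − log10(treated area)`, the control mean
taken on the **linear** area scale over all same-experiment control FOVs at
that time (a warning notes departures from the conventional two control
FOVs). `mean_lr()` pools points with equal weight by default — appropriate
for near-balanced data — and offers per-series averaging for unbalanced
studies. Interior analysis windows are right-open and a study's final
window closed; `right_open` exposes that choice.

Treatment variability is not constant: repeatability variance rises and
falls as a frown-shaped function of the LR, small for both ineffective and
overwhelming treatments. `fit_variance_trend()` fits the OLS quadratic
(unweighted by default; weights, e.g. FOV counts, optional) and
`predict_components()` turns an anticipated LR into plug-in variance
components. Because the split of the LR variance into levels is not
identified by the trend alone, proportions must be supplied; the default of
equal thirds is a loud-warning fallback, not a recommendation. For LR
designs the inflation factor defaults to `c = 12`, the maximum observed for
the reference LR data, when not estimated.

## Synthetic data

`simulate_growth()` generates the structure the estimators assume: a
piecewise-linear mean in log10 area (lag slope to `lag_end_h`, then an
exponential-phase slope — linear-in-log is exactly what the hour-wise LMM
with a time covariate assumes, so no mechanistic logistic curve is
attempted), plus Gaussian experiment and FOV intercepts and a stationary
AR(1) residual (initialized from the stationary distribution so the first
frame is a full-variance draw). Defaults are the early-exponential reference
conditions: 4-h course, 3-min frames, baseline 2.5 log10 area units, slopes
0.1 and 0.5 log10/h with the phase change at 2 h, level SDs
(0.2433, 0.2023, 0.0373) — the square roots of proportion × repeatability
SD² of the early profile — and phi = 0.8751. `simulate_paired_study()`
shares experiment intercepts between arms (paired wells in one dish),
subtracts a target LR curve from the treated mean, and draws independent
FOV/time noise per arm, so `compute_lr()` recovers the target in
expectation.

What the generator does *not* emulate: FOV selection bias (real FOVs are
chosen to contain bacteria, not at random), non-Gaussian aggregate-driven
jumps, phototoxic drift, or LR-dependent variance. Parameter-recovery tests
on this generator therefore show estimator correctness under the assumed
model, not robustness to those realities.

For the antibiotic-like validation scenario (target mean LR 0.8 with LR
repeatability SD ≈ 0.12), noise levels were derived analytically from
Var(LR) ≈ (1 + 1/n_ctrl)(sd_fov² + sd_time²): `sd_fov = 0.06`,
`sd_time = 0.085` with three control FOVs give an LR SD of ≈ 0.12.

## Bootstrap validation of a design

`bootstrap_studies()` keeps the experiments of a pilot dataset fixed and
resamples, uniformly with replacement within each experiment, the FOVs a
smaller candidate design would have collected (default one control + one
treated). Per study it computes per-experiment mean LRs over the analysis
window, the study mean, the between-experiment SEM `sd/sqrt(n_exp)` — the
natural single-FOV-per-experiment reduction of the design SEM, chosen
because the resampling scheme does not re-estimate within-experiment
components — the one-sided MOE, lower limit, and the significant-kill flag
(`mean LR − MOE > 0`, ties not detected). `enumerate_combinations()`
materializes the exact draw space (e.g. 729 draws for 3 experiments × 3 + 3
FOVs) for exhaustive checks; the bootstrap mean converges to the
enumeration average. The default window is the final hour of the series,
matching the convention of reading out a 4-h treatment contact over hours
3–4.

## Numerical and testing choices

* Tolerances: design-table cells recomputed from the rounded published
  profiles agree with printed values to within 1% relative; that rounding,
  not the algebra, is the binding error source.
* Parameter-recovery Monte-Carlo sizes were chosen to keep the default test
  suite compact while leaving comfortable statistical margins: 20-replicate
  recovery at the 6 × 2 × 20 design (30% tolerance per component SD) and a
  200-replicate relative-bias check (<10% per variance component), run at
  phi = 0 because the REML estimator's own model assumes exchangeable
  residuals; AR(1) recovery is tested separately on long single series.
* Degenerate inputs: constant responses return all-zero components directly
  (the mixed model is singular there); zero/negative areas are rejected at
  ingest with row numbers; serial correlations outside (−1, 1) are clamped
  with a warning; negative trend predictions are clipped at zero.
* Determinism: every stochastic function takes a `seed` argument and is
  bit-reproducible given it.

## Limitations

The design formulas assume balanced designs and Gaussian components; the
0.5-df single-experiment convention is a pragmatic approximation with no
distributional derivation; variance profiles from one laboratory system
transfer to another only approximately, and the packaged profiles should be
replaced by pilot-data estimates whenever possible.
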