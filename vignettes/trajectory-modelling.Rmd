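---
title: "Distributional trajectory models for perinatal plasma proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distributional trajectory models for perinatal plasma proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periprot)
```

## The problem

Serum albumin and plasma alpha-1-acid glycoprotein (AAG) are the two major
drug-binding proteins in plasma. Their concentrations change through
pregnancy and the postpartum period, which changes the unbound fraction of
many drugs and therefore matters for dosing. Physiologically based
pharmacokinetic (PBPK) platforms need these trajectories — not just a mean
curve, but the full distribution of concentrations at each time, so that
virtual populations can be sampled realistically.

`periprot` implements a distributional-regression workflow for such data:
longitudinal concentration measurements, sparsely sampled (most subjects
contribute one or two samples), observed over gestational age (weeks) in
pregnancy or over weeks after delivery postpartum.

## The model

For a single analyte and period, observations \((t_i, y_i)\) are treated as
independent draws

\[ y_i \sim \mathcal{F}\bigl(\mu(t_i),\ \sigma(t_i),\ \theta\bigr), \]

where \(\mu(\cdot)\) is a penalized B-spline (P-spline) location curve,
\(\sigma(\cdot)\) an error-scale model and \(\theta\) optional shape
parameters of the error family \(\mathcal{F}\). Three families are
available:

* **normal** — the symmetric baseline;
* **two-component normal mixture** (`mixture2`) — captures a heavy lower
  shoulder; parameterized by component-mean offsets constrained to zero
  weighted mean, so the location curve *is* the arithmetic-mean curve;
* **two-piece ("split", skew normal type 2) normal** (`two_piece`) —
  density \(c\,\varphi(\nu(y-\mu)/\sigma)\) below the split point \(\mu\)
  and \(c\,\varphi((y-\mu)/(\nu\sigma))\) above it, with
  \(c = 2/(\sigma(\nu + 1/\nu))\). \(\nu<1\) gives negative (left) skew;
  at \(\nu = 1\) it reduces exactly to the normal. This parameterization was
  chosen because it has closed-form CDF, quantile and mean
  (\(E[Y] = \mu + \sigma\sqrt{2/\pi}(\nu - 1/\nu)\)), which the exported
  computational functions rely on.

Variance models for \(\sigma(t)\): `constant`, `piecewise_constant` (one
breakpoint; the postpartum albumin default places it at 0.5 weeks after
delivery, configurable), and `smooth_in_time`, implemented as log-linear in
time. The mixture family is restricted to constant variance so that its EM
updates stay closed-form; time-varying dispersion alternatives are
representable through the normal and two-piece families, which is how the
candidate sets in `pipeline_config()` are assembled.

For the two-piece family the spline models the split point \(\mu(t)\);
`mean_curve()` adds the closed-form mean offset, so the reported
arithmetic-mean curve always equals the mean of the local error
distribution. A side effect worth knowing: with a piecewise error SD the
mean curve inherits a small step at the breakpoint even though \(\mu(t)\)
is smooth.

## Fitting

`fit_trajectory_model()` alternates

1. a penalized weighted least-squares update of the location coefficients
   given the current scale/shape (for the mixture, with EM
   responsibilities as weights and an expectation-weighted working
   response), and
2. a maximum-likelihood update of the scale and shape given the location
   curve (closed-form for the normal and for per-segment piecewise scales;
   Nelder–Mead for the two-piece shape and the log-linear variance
   coefficients).

The monitored objective is the penalized log-likelihood
\(\ell - \tfrac{1}{2}\lambda^{*} c^{\top} D^{\top}D c\), with \(D\) the
difference matrix; it is nondecreasing across iterations by construction
(EM inequality for the mixture; exact maximization for the normal;
step-halving toward the previous iterate for the two-piece, whose working
weights depend on residual signs). Iteration stops when the relative change
falls below `1e-8` (cap 500 iterations; non-convergence returns the last
iterate with `converged = FALSE` and a warning).

Numerical choices:

* **Basis**: 20 equally spaced interior knots, cubic, over the observed
  time range, with knots extended beyond the boundary in the P-spline
  convention so that straight lines lie exactly in the null space of the
  order-2 difference penalty. Evaluation outside the fitted domain is an
  error everywhere in the package — these models never extrapolate.
* **Smoothing weight** \(\lambda\): chosen once by generalized AIC
  (Gaussian working likelihood) on a 41-point log grid over
  \([10^{-4}, 10^{8}]\) with one golden-section refinement, on a
  preliminary normal fit, then held fixed during the alternation. Grid ties
  go to the larger (smoother) \(\lambda\). \(\lambda^{*}\) rescales
  \(\lambda\) by the preliminary residual variance so the penalty lives on
  the log-likelihood scale.
* **Scale floor**: \(10^{-6}\,\mathrm{sd}(y)\) guards against degenerate
  spikes (e.g. EM components collapsing onto single points).
* **Mixture starts**: a deterministic median split of preliminary
  residuals plus four random responsibility draws (seeded); each is run for
  40 iterations and the best is continued to convergence.
* **Mixture quantile**: bisection on the CDF, bracket at \(\pm 10\)
  combined SDs, tolerance \(10^{-10}\) in probability.

Effective degrees of freedom are the trace of the final weighted smoother
matrix plus one per free scale/shape parameter;
`gaic()` is \(-2\ell + k\,\mathrm{edf}\) with \(k = 2\) by default.

## Model selection and validation

`select_model()` walks the candidate list from simplest to most complex and
lets a more complex model displace the current one only when its GAIC is
lower by more than `delta` (default 2.034). The default encodes a
documented parsimony judgment — a time-varying-variance alternative whose
AIC is better by almost exactly that margin is still rejected in favour of
constant variance — and is user-overridable.

Validation is by quantile-coverage concordance: `quantile_curves()`
evaluates the family quantile at the local parameters over a time grid
(default percentiles 2.5, 10, 25, 50, 75, 90, 97.5), and
`coverage_table()` reports the percentage of observations strictly below
each curve at their own times. Ties count as not-below; under the
continuous families they have probability zero, so the convention is
innocuous. `quantile_residual_diagnostics()` supplies normalized quantile
residuals \(\Phi^{-1}(F(y_i \mid t_i))\) with a QQ deviation statistic for
family comparison.

Sparse analytes (AAG, with fewer than forty observations per period) get a
deliberately simpler treatment: `fit_cubic_smoothing_spline()` — a natural
cubic smoothing spline with GCV (leave-one-out CV behind a flag), duplicate
times averaged with multiplicity weights — models the central tendency
only, and the exported bundle is mean-only.

## Computational functions

`approximate_mean_polynomial()` converts a fitted mean curve into a
polynomial by increasing the degree until \(R^2 > 0.995\) against the curve
sampled on a 0.1-week grid (degree cap 10, explicit failure beyond it).
`build_function_set()` packages the polynomial with the family, shape and
variance model; `quantile_function_eval()` inverts the family mean formula
to recover the location before applying the family quantile, and
`sample_virtual_population()` draws (time, concentration) pairs from a
configurable time sampler — the generator PBPK users need. Bundles
round-trip through schema-versioned JSON exactly.

One known limitation, found while validating the postpartum albumin
pipeline: a global \(R^2\) criterion does not bound the pointwise error.
For the postpartum mean curve (steep early rise plus the small step at the
variance breakpoint) the first accepted polynomial can deviate by ~3% of
the curve range in the sup norm even though \(R^2 > 0.995\); for smooth
curves like the pregnancy trajectory the deviation is far below 2%. Users
who need uniform accuracy should raise `r2_threshold`.

## The synthetic-data generator

The restricted nature of real perinatal cohort data motivates a first-class
generator. `trajectory_preset()` fixes "true" mean curves through the
reported anchor values — pregnancy albumin linear through (20 wk, 34.3 g/L)
and (37 wk, 33.4 g/L); postpartum albumin as the exponential saturation
\(42.3 - 10.7e^{-kt}\) with \(k = \log(10.7/4)/3\) so that delivery, 3-week
and plateau anchors (31.6, 38.3, 42.3 g/L) hold exactly; AAG linear through
its two anchors per period. The saturating form is a preset choice made
because three anchors and no functional form are reported; it is not a
claim about the shape of any fitted spline. Error families follow the
models the analysis is designed to select (mixture in pregnancy, left-skew
two-piece with piecewise SDs 4.86/3.64 g/L postpartum); shape values not
reported anywhere are declared defaults and carry a `not_from_literature`
flag.

`default_study_design()` reproduces the cohort structure: 380 pregnant /
354 postpartum subjects for albumin (about 850 and 760 samples), visit
windows at 20–26 and 30–38 weeks gestation plus late-gestation draws, a
delivery sample at \(t = 0\) postpartum with follow-up to 46 weeks, a
samples-per-subject distribution under which roughly 70% of subjects
contribute at most two samples, and one injected implausible outlier
(> 60 g/L) per albumin dataset, which `exclude_outliers()` removes at the
default 60 g/L threshold.

What the generator does *not* emulate: within-subject correlation (the
analysis, like the generator, assumes independence — an explicit modelling
simplification), covariates such as race, weight or antiretroviral
regimen, assay error structure, and informative visit timing. Passing
coverage and recovery tests on this synthetic data therefore demonstrates
internal consistency of the estimator under its own assumptions, not
robustness to those real-data features.

## Problem sizes used in the test-suite

Simulation-backed tests run at n = 800 observations per fit (matching the
albumin cohorts' scale), 10 seeds for coverage calibration, 20 replicates
for skew/scale recovery, and \(10^6\) draws for Monte-Carlo moment checks —
sizes at which the binomial and CLT tolerances used in the assertions are
meaningful.

## A worked run

```{r, eval = FALSE}
cfg <- pipeline_config("albumin", "postpartum", seed = 11)
out <- run_pipeline(cfg, out_dir = "pp_run")
out$fit                      # selected family, GAIC, edf
out$coverage                 # nominal vs observed percent below each curve
mean_function_eval(out$function_set, 0)   # estimated mean at delivery
```

## Limitations

* Observations are treated as independent; repeated measures from the same
  subject are not modelled (no random effects), so interval estimates can
  be optimistic for subjects with many samples.
* Only time enters the model; no covariate effects.
* No extrapolation beyond the observed time range, by design.
* The mixture family's variance must be constant; dispersion-in-time
  questions should be posed through the normal or two-piece candidates.
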