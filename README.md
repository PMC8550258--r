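# periprot

Distributional trajectory models for serum albumin and plasma
alpha-1-acid glycoprotein (AAG) in pregnant and postpartum women.

Albumin and AAG are the major drug-binding proteins in plasma, and both
shift substantially across pregnancy and after delivery. Physiologically
based pharmacokinetic (PBPK) platforms need not only the mean trajectory of
each protein but its full concentration distribution over time, so that
virtual populations can be sampled with realistic spread and skew.
`periprot` is aimed at pharmacometricians and biostatisticians who fit such
trajectories from sparse longitudinal cohort data and export them in a form
PBPK tools can consume.

## The model

For observations $(t_i, y_i)$ of one analyte in one period,

$$ y_i \sim \mathcal{F}\left(\mu(t_i),\, \sigma(t_i),\, \theta\right), $$

with $\mu(t)$ a penalized B-spline (P-spline: cubic basis, 20 interior
knots, order-2 difference penalty, smoothing weight chosen by generalized
AIC), $\sigma(t)$ constant, piecewise-constant or log-linear in time, and
$\mathcal{F}$ one of three error families: normal, a mean-constrained
two-component normal mixture, or the two-piece (split) normal

$$ f(y) = \frac{2}{\sigma(\nu + 1/\nu)}\,
   \varphi\!\left(\frac{\nu (y-\mu)}{\sigma}\right) \; (y<\mu), \qquad
   \varphi\!\left(\frac{y-\mu}{\nu\sigma}\right) \; (y\ge\mu), $$

which is left-skewed for $\nu < 1$ and has closed-form CDF, quantiles and
mean $\mu + \sigma\sqrt{2/\pi}\,(\nu - 1/\nu)$. Candidate models are
compared by generalized AIC with a parsimony margin (a more complex model
must win by more than `delta = 2.034` to displace a simpler one), and the
selected model is validated by quantile-coverage concordance: the percent
of observations falling below each fitted percentile curve (2.5th through
97.5th) should match the nominal levels. Sparse AAG data are fit with a
GCV cubic smoothing spline for the mean only. Fitted mean curves are
approximated by the lowest-degree polynomial reaching $R^2 > 0.995$, and
exported with the family parameters as JSON "computational function"
bundles providing mean, quantile and virtual-population sampling functions.

A seeded synthetic-data generator reproduces the structure of the
motivating cohort study (around 380 pregnant and 354 postpartum subjects,
mostly one or two samples each, protocol visit windows, rare implausible
outliers above 60 g/L), so the whole pipeline is testable without
access-restricted patient data.

## Worked example

```r
library(periprot)

cfg <- pipeline_config("albumin", "postpartum", seed = 11)
out <- run_pipeline(cfg, out_dir = "pp_run")   # simulates, fits, selects
out$fit
#> <trajectory_fit> family = two_piece | variance = piecewise_constant
#>   n = 725 | domain = [ 0 , 45.57237 ] wks
#>   loglik = -2084.92 | edf = 10.14 | GAIC(k= 2 ) = 4190.11
```

On synthetic postpartum albumin data the pipeline selects the left-skewed
two-piece family with different error SDs up to and beyond 0.5 weeks after
delivery — the structure the generator embeds. The coverage table shows the
calibration of the seven percentile curves on the training data:

```r
out$coverage
#>   nominal  observed
#> 1     2.5  2.344828
#> 2    10.0 10.206897
#> 3    25.0 23.862069
#> 4    50.0 48.551724
#> 5    75.0 75.586207
#> 6    90.0 90.620690
#> 7    97.5 97.517241
```

The exported function set evaluates the polynomial mean and the family
quantiles anywhere in the fitted domain:

```r
mean_function_eval(out$function_set, 0)    # 31.9 g/L at delivery
mean_function_eval(out$function_set, 15)   # 42.6 g/L near the plateau
quantile_function_eval(out$function_set, 15, 0.975)   # 48.6 g/L
sample_virtual_population(out$function_set, 10000, seed = 1)
```

The estimated mean rises from about 31.9 g/L at delivery toward a plateau
of about 42.6 g/L — recovering the generator's true anchors (31.6 and
42.3 g/L) to within a few tenths of a g/L. Artifacts (`model.json`,
`quantiles.csv`, `coverage.csv`, `bundle.json`, `pipeline_log.txt`) land in
`out_dir`, and reruns with the same seed are identical apart from the
provenance timestamp.

For distributional comparisons against published reference equations,
`tail_probability_analytic()` / `tail_probability_mc()` compute threshold
exceedance probabilities (analytically and by seeded simulation) and
`percent_of_plateau()` expresses concentrations relative to a plateau
value; printed point evaluations of the reference equations ship as
validation fixtures (`reference_anchors()`).

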