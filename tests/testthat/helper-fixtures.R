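# Shared fixtures, built once per test session and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# pregnancy albumin dataset (outliers removed) and its mixture fit
fix_preg_data <- function() fixture("preg_data", function() {
  pre <- trajectory_preset("albumin_pregnancy")
  d <- generate_dataset(default_study_design(pre), pre, seed = 101)
  exclude_outliers(d)$data
})

fix_preg_mixture_fit <- function() fixture("preg_mixture_fit", function() {
  fit_trajectory_model(fix_preg_data(), model_spec("mixture2"), seed = 1)
})

# postpartum albumin dataset and its two-piece, piecewise-variance fit
fix_pp_data <- function() fixture("pp_data", function() {
  pre <- trajectory_preset("albumin_postpartum")
  d <- generate_dataset(default_study_design(pre), pre, seed = 202)
  exclude_outliers(d)$data
})

fix_pp_twopiece_fit <- function() fixture("pp_twopiece_fit", function() {
  fit_trajectory_model(
    fix_pp_data(),
    model_spec("two_piece", variance_model("piecewise_constant", 0.5)),
    seed = 1)
})

# simple smooth test function on [0, 10]
smooth_curve <- function(t) 34 + 2 * sin(t / 2) - 0.1 * t

# normal-noise dataset around smooth_curve
make_normal_data <- function(n, sigma, seed) {
  set.seed(seed)
  t <- runif(n, 0, 10)
  data.frame(time = t, concentration = smooth_curve(t) + rnorm(n, 0, sigma))
}

# two-piece-noise dataset around smooth_curve (mode-centred)
make_twopiece_data <- function(n, sigma, skew, seed) {
  set.seed(seed)
  t <- runif(n, 0, 10)
  spec <- dist_two_piece(0, sigma, skew)
  data.frame(time = t,
             concentration = smooth_curve(t) + dist_sample(spec, n))
}

empirical_skewness <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / stats::sd(x)^3
}
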