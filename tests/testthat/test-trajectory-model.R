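test_that("observation sets enforce units, periods and protocol windows", {
  ok <- data.frame(subject_id = "a", analyte = "albumin",
                   period = "pregnancy", time = 25, concentration = 34)
  expect_s3_class(observation_set(ok), "observation_set")
  bad_t <- ok; bad_t$time <- 15
  expect_error(observation_set(bad_t), "20, 43")
  bad_c <- ok; bad_c$concentration <- -1
  expect_error(observation_set(bad_c), "positive")
  expect_error(observation_set(ok[, -1, drop = FALSE]), "missing column")
  bad_a <- ok; bad_a$analyte <- "crp"
  expect_error(observation_set(bad_a), "analyte")
  expect_error(model_spec("mixture2", variance_model("smooth_in_time")),
               "constant")
  expect_error(variance_model("piecewise_constant"), "breakpoint")
})

test_that("normal-noise data: the fitted mean curve recovers the truth", {
  sigma <- 3
  d <- make_normal_data(800, sigma, seed = 31)
  fit <- fit_trajectory_model(d, model_spec("normal"), seed = 1)
  expect_true(fit$converged)
  g <- seq(0.2, 9.8, length.out = 80)
  rmse <- sqrt(mean((mean_curve(fit, g) - smooth_curve(g))^2))
  expect_lt(rmse, sigma / 5)
  expect_lt(abs(fit$variance$scales - sigma) / sigma, 0.10)
  # mean curve equals the mean of the local distribution everywhere
  mns <- vapply(g, function(tt) dist_mean(local_spec(fit, tt)), numeric(1))
  expect_equal(mean_curve(fit, g), mns, tolerance = 1e-8)
})

test_that("two-piece noise: skew and scale are recovered", {
  hits <- 0
  for (s in 1:3) {
    d <- make_twopiece_data(800, sigma = 4, skew = 0.8, seed = 40 + s)
    fit <- fit_trajectory_model(d, model_spec("two_piece"), seed = 1)
    ok <- fit$shape$skew > 0.6 && fit$shape$skew < 1.0 &&
      abs(fit$variance$scales - 4) / 4 < 0.10
    hits <- hits + ok
  }
  expect_gte(hits, 2)
})

test_that("constant data collapses to a constant mean and floor scale", {
  d <- data.frame(time = seq(0, 10, length.out = 50),
                  concentration = rep(34, 50))
  fit <- suppressWarnings(fit_trajectory_model(d, model_spec("normal"),
                                               seed = 1))
  expect_equal(unname(mean_curve(fit, c(1, 5, 9))), rep(34, 3),
               tolerance = 1e-6)
  expect_lt(fit$variance$scales, 1e-6)
})

test_that("penalized log-likelihood is nondecreasing across iterations", {
  for (fit in list(fix_preg_mixture_fit(), fix_pp_twopiece_fit())) {
    tr <- fit$loglik_trace
    expect_true(all(diff(tr) > -1e-6 * (1 + abs(tr[-length(tr)]))))
  }
})

test_that("gaic does the stated arithmetic and respects nesting", {
  m <- list(loglik = -100, edf = 5)
  expect_equal(gaic(m, k = 2), 210)
  expect_equal(gaic(m, k = 0), 200)
  expect_error(gaic(list(loglik = NaN, edf = 2)), "finite")
  # nested models on the same data: the larger model fits at least as well
  d <- make_normal_data(300, 2, seed = 55)
  small <- fit_trajectory_model(d, model_spec("normal"), seed = 1)
  big <- fit_trajectory_model(
    d, model_spec("normal", variance_model("smooth_in_time")),
    lambda = small$lambda, seed = 1)
  expect_gte(big$loglik, small$loglik - 1e-6)
})

test_that("model selection demands a material GAIC gain from complexity", {
  simple <- list(loglik = -50, edf = 0, family = "normal")     # gaic 100
  at_margin <- list(loglik = -(100 - 2.034) / 2, edf = 0,
                    family = "two_piece")                      # gaic 97.966
  clearly <- list(loglik = -47.5, edf = 0, family = "two_piece") # gaic 95
  sel1 <- select_model(list(simple, at_margin))
  expect_identical(sel1$family, "normal")   # improvement == delta: keep simple
  sel2 <- select_model(list(simple, clearly))
  expect_identical(sel2$family, "two_piece")
  sel3 <- select_model(list(simple))
  expect_identical(sel3$family, "normal")
  expect_error(select_model(list()), "empty")
  expect_s3_class(attr(sel1, "gaic_table"), "data.frame")
})

test_that("family selection has power and respects parsimony", {
  prefer_skew <- 0
  prefer_normal <- 0
  n_seeds <- 6
  for (s in seq_len(n_seeds)) {
    dsk <- make_twopiece_data(800, 4, 0.8, seed = 600 + s)
    cands <- list(fit_trajectory_model(dsk, model_spec("normal"), seed = 1),
                  fit_trajectory_model(dsk, model_spec("two_piece"), seed = 1))
    if (select_model(cands)$family == "two_piece") prefer_skew <- prefer_skew + 1
    dn <- make_normal_data(800, 4, seed = 700 + s)
    cands <- list(fit_trajectory_model(dn, model_spec("normal"), seed = 1),
                  fit_trajectory_model(dn, model_spec("two_piece"), seed = 1))
    if (select_model(cands)$family == "normal") prefer_normal <- prefer_normal + 1
  }
  expect_gte(prefer_skew, n_seeds - 1)
  expect_gte(prefer_normal, n_seeds - 1)
})

test_that("quantile curves are ordered and reflect the left skew", {
  fit <- fix_pp_twopiece_fit()
  qc <- quantile_curves(fit, probs = c(0.025, 0.25, 0.5, 0.75, 0.975))
  expect_true(all(apply(as.matrix(qc[-1]), 1, function(r) all(diff(r) > 0))))
  # left skew: lower percentiles are farther apart than upper ones
  expect_true(all((qc$q50 - qc$q25) > (qc$q75 - qc$q50)))
  # normal family: the median curve is the mean curve
  nf <- fit_trajectory_model(make_normal_data(400, 2, seed = 77),
                             model_spec("normal"), seed = 1)
  g <- seq(0.5, 9.5, length.out = 40)
  qn <- quantile_curves(nf, probs = c(0.5), grid = g)
  expect_equal(qn$q50, mean_curve(nf, g), tolerance = 1e-8)
  expect_error(quantile_curves(fit, probs = c(0.5, 0.25)), "increasing")
  expect_error(quantile_curves(fit, grid = fit$domain[2] + 5), "domain")
})

test_that("2.5/97.5 curves bracket about 95% of fresh model draws", {
  fit <- fix_preg_mixture_fit()
  set.seed(91)
  t <- runif(4000, fit$domain[1], fit$domain[2])
  y <- vapply(t, function(tt) dist_sample(local_spec(fit, tt), 1),
              numeric(1))
  d <- data.frame(time = t, concentration = pmax(y, 0.1))
  cov <- coverage_table(fit, d, probs = c(0.025, 0.975))
  inside <- cov$observed[2] - cov$observed[1]
  expect_gt(inside, 93)
  expect_lt(inside, 97)
})

test_that("coverage counts strictly-below with ties counted as not-below", {
  fit <- fix_preg_mixture_fit()
  t <- seq(21, 41, length.out = 50)
  below <- data.frame(time = t, concentration = rep(1, 50))
  cov <- coverage_table(fit, below, probs = c(0.025, 0.5, 0.975))
  expect_equal(cov$observed, rep(100, 3))
  on_curve <- data.frame(time = t,
                         concentration = quantile_curves(fit, 0.5, t)$q50)
  cov2 <- coverage_table(fit, on_curve, probs = 0.5)
  expect_equal(cov2$observed, 0)   # exactly on the curve is not below it
  expect_error(coverage_table(fit, below[0, ]), "empty")
  expect_true(all(diff(coverage_table(fit, fix_preg_data())$observed) >= 0))
})

test_that("quantile residuals are standard normal under the true model", {
  fit <- fix_preg_mixture_fit()
  set.seed(123)
  t <- runif(800, fit$domain[1], fit$domain[2])
  y <- vapply(t, function(tt) dist_sample(local_spec(fit, tt), 1), numeric(1))
  qr <- quantile_residual_diagnostics(fit, data.frame(time = t,
                                                      concentration = pmax(y, 0.1)))
  expect_lt(abs(qr$mean), 0.1)
  expect_lt(abs(qr$variance - 1), 0.15)
  # a single observation at its own median has residual zero
  tmid <- mean(fit$domain)
  med <- dist_quantile(local_spec(fit, tmid), 0.5)
  one <- quantile_residual_diagnostics(fit, data.frame(time = tmid,
                                                       concentration = med))
  expect_equal(one$residuals, 0, tolerance = 1e-7)
})

test_that("misspecified families show larger QQ deviations than correct ones", {
  wins <- 0
  n_rep <- 8
  for (s in seq_len(n_rep)) {
    d <- make_twopiece_data(800, 4, 0.7, seed = 800 + s)
    fn <- fit_trajectory_model(d, model_spec("normal"), seed = 1)
    ft <- fit_trajectory_model(d, model_spec("two_piece"), seed = 1)
    qn <- quantile_residual_diagnostics(fn, d)$qq_stat
    qt <- quantile_residual_diagnostics(ft, d)$qq_stat
    if (qn > qt) wins <- wins + 1
  }
  expect_gte(wins, n_rep - 2)
})

test_that("outlier exclusion removes only implausible records", {
  d <- data.frame(subject_id = c("a", "b", "c"), analyte = "albumin",
                  period = "pregnancy", time = c(22, 30, 35),
                  concentration = c(34, 36, 61))
  r <- exclude_outliers(observation_set(d), 60)
  expect_equal(r$n_excluded, 1)
  expect_equal(nrow(r$data), 2)
  r2 <- exclude_outliers(d, Inf)
  expect_equal(r2$n_excluded, 0)
  expect_equal(nrow(r2$data), 3)
  expect_error(exclude_outliers(d, -5), "positive")
})
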