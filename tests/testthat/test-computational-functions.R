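make_linear_fs <- function(family = "normal", shape = NULL,
                           variance = list(kind = "constant", scales = 2),
                           coef = c(10, 2), domain = c(0, 10)) {
  pa <- structure(list(coefficients = coef, degree = length(coef) - 1,
                       r_squared = 1, domain = domain),
                  class = "poly_approx")
  computational_function_set("albumin", "postpartum", pa, family = family,
                             shape = shape, variance = variance,
                             provenance = list(fit_id = "synthetic", seed = 1))
}

test_that("polynomial approximation stops at the first adequate degree", {
  lin <- approximate_mean_polynomial(function(t) 10 + 2 * t, c(0, 10))
  expect_equal(lin$degree, 1)
  expect_equal(lin$r_squared, 1, tolerance = 1e-12)
  expect_equal(lin$coefficients, c(10, 2), tolerance = 1e-8)
  # one period of a sine needs a high degree
  sn <- approximate_mean_polynomial(sin, c(0, 2 * pi), r2_threshold = 0.995)
  expect_gte(sn$degree, 5)
  expect_gt(sn$r_squared, 0.995)
  # least-squares oracle at the accepted degree reproduces the R^2
  g <- seq(0, 2 * pi, by = 0.1); if (max(g) < 2 * pi) g <- c(g, 2 * pi)
  o <- lm(sin(g) ~ poly(g, sn$degree, raw = TRUE))
  expect_equal(sn$r_squared, summary(o)$r.squared, tolerance = 1e-8)
  # near-quadratic curve is accepted at degree 2
  qd <- approximate_mean_polynomial(function(t) 1 + t - 0.3 * t^2 +
                                      1e-4 * sin(40 * t), c(0, 10))
  expect_equal(qd$degree, 2)
  # degree cap: explicit failure reporting the best R^2
  expect_error(
    approximate_mean_polynomial(function(t) ifelse(t < 5, 0, 1), c(0, 10),
                                r2_threshold = 0.99999),
    "best R\\^2")
})

test_that("polynomial evaluation honors the closed domain", {
  pa <- approximate_mean_polynomial(function(t) 10 + 2 * t, c(0, 10))
  expect_equal(eval_polynomial(pa, 5), 20, tolerance = 1e-8)
  expect_equal(eval_polynomial(pa, 10), 30, tolerance = 1e-8)  # closed at hi
  expect_error(eval_polynomial(pa, 10.01), "outside")
  fs <- make_linear_fs()
  expect_equal(mean_function_eval(fs, 5), 20, tolerance = 1e-8)
  expect_error(mean_function_eval(fs, -1), "outside")
})

test_that("quantile function inverts the family mean correctly", {
  fs_n <- make_linear_fs("normal")
  t <- c(1, 4, 9)
  expect_equal(quantile_function_eval(fs_n, t, 0.5),
               mean_function_eval(fs_n, t), tolerance = 1e-10)
  expect_true(all(quantile_function_eval(fs_n, t, 0.975) >
                    quantile_function_eval(fs_n, t, 0.5)))
  # left-skewed two-piece: median above mean
  fs_t <- make_linear_fs("two_piece", shape = list(skew = 0.8),
                         variance = list(kind = "constant", scales = 3))
  expect_true(all(quantile_function_eval(fs_t, t, 0.5) >
                    mean_function_eval(fs_t, t)))
  # inversion consistency with the distribution module at one time point
  m <- mean_function_eval(fs_t, 4)
  mode <- m - 3 * sqrt(2 / pi) * (0.8 - 1 / 0.8)
  sp <- dist_two_piece(mode, 3, 0.8)
  expect_equal(dist_mean(sp), m, tolerance = 1e-10)
  expect_equal(quantile_function_eval(fs_t, 4, 0.9), dist_quantile(sp, 0.9),
               tolerance = 1e-10)
  expect_error(quantile_function_eval(fs_n, 4, 1.5), "probability")
})

test_that("virtual-population sampling is seeded and calibrated", {
  fs <- make_linear_fs("two_piece", shape = list(skew = 0.8),
                       variance = list(kind = "constant", scales = 3))
  a <- sample_virtual_population(fs, 10000, seed = 21)
  b <- sample_virtual_population(fs, 10000, seed = 21)
  expect_identical(a, b)
  expect_true(all(a$time >= 0 & a$time <= 10))
  one <- sample_virtual_population(fs, 1, seed = 3)
  expect_equal(nrow(one), 1)
  # degenerate time sampler: empirical quantiles match the quantile function
  vp <- sample_virtual_population(fs, 1e5,
                                  time_sampler = list(kind = "fixed", time = 5),
                                  seed = 77)
  for (p in c(0.1, 0.5, 0.9)) {
    q <- quantile_function_eval(fs, 5, p)
    expect_lt(abs(mean(vp$concentration < q) - p), 0.005)
  }
  emp <- sample_virtual_population(
    fs, 500, time_sampler = list(kind = "empirical", times = c(1, 2, 3)),
    seed = 5)
  expect_true(all(emp$time %in% c(1, 2, 3)))
})

test_that("JSON bundles round-trip exactly and validate their schema", {
  fit <- fix_pp_twopiece_fit()
  fs <- build_function_set(fit, "albumin", "postpartum", seed = 1)
  json <- export_function_bundle(fs)
  fs2 <- import_function_bundle(json)
  tt <- seq(fs$domain[1], fs$domain[2], length.out = 100)
  expect_equal(mean_function_eval(fs2, tt), mean_function_eval(fs, tt),
               tolerance = 1e-12)
  for (p in c(0.025, 0.5, 0.975)) {
    expect_equal(quantile_function_eval(fs2, tt, p),
                 quantile_function_eval(fs, tt, p), tolerance = 1e-12)
  }
  expect_identical(fs2$provenance$seed, 1L)
  # file round trip
  path <- tempfile(fileext = ".json")
  export_function_bundle(fs, path)
  expect_equal(mean_function_eval(import_function_bundle(path), tt),
               mean_function_eval(fs, tt), tolerance = 1e-12)
  # missing blocks are named in the error
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  doc$variance_model <- NULL
  expect_error(import_function_bundle(jsonlite::toJSON(doc, auto_unbox = TRUE)),
               "variance_model")
  doc2 <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  doc2$mean_polynomial$coefficients <- NULL
  expect_error(import_function_bundle(jsonlite::toJSON(doc2, auto_unbox = TRUE)),
               "mean_polynomial.coefficients")
  doc3 <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  doc3$schema_version <- "9.9"
  expect_error(import_function_bundle(jsonlite::toJSON(doc3, auto_unbox = TRUE)),
               "schema version")
})

test_that("exported bundles keep ordered quantiles and a bracketed mean", {
  for (fit in list(fix_preg_mixture_fit(), fix_pp_twopiece_fit())) {
    fs <- build_function_set(fit, "albumin",
                             if (fit$family == "mixture2") "pregnancy"
                             else "postpartum")
    expect_gt(fs$mean_poly$r_squared, 0.995)
    tt <- seq(fs$domain[1], fs$domain[2], length.out = 60)
    qs <- sapply(c(0.025, 0.10, 0.25, 0.50, 0.75, 0.90, 0.975),
                 function(p) quantile_function_eval(fs, tt, p))
    expect_true(all(apply(qs, 1, function(r) all(diff(r) > 0))))
    m <- mean_function_eval(fs, tt)
    expect_true(all(m > qs[, 1] & m < qs[, 7]))
    # polynomial stays close to the nonparametric curve it approximates:
    # within 2% of the curve range when the curve is smooth (pregnancy), and
    # in general within 4x the RMS deviation implied by the achieved R^2
    # (the postpartum mean curve has a step at the variance breakpoint, so a
    # uniform 2% bound is not attainable there by any polynomial)
    npar <- mean_curve(fit, tt)
    if (fit$family == "mixture2") {
      expect_lt(max(abs(m - npar)), 0.02 * diff(range(npar)) + 1e-8)
    }
    rms_bound <- sqrt(1 - fs$mean_poly$r_squared) * sd(npar)
    expect_lt(max(abs(m - npar)), 4 * rms_bound + 1e-8)
  }
})
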