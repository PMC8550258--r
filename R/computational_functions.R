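#' Polynomial approximation of a fitted mean curve
#'
#' Fits least-squares polynomials of increasing degree to the curve evaluated
#' on a regular grid, accepting the first degree whose coefficient of
#' determination against the grid values exceeds `r2_threshold`. This turns a
#' nonparametric mean curve into a cheap closed-form expression suitable for
#' PBPK platforms.
#'
#' @param curve A function of time, or a `trajectory_fit` / `smooth_fit`
#'   (its `mean_curve` / `evaluate` is used).
#' @param domain Length-2 numeric, the closed time domain (weeks).
#' @param r2_threshold Acceptance threshold for R-squared, in (0, 1).
#' @param step Grid step in weeks.
#' @param max_degree Degree cap; exceeding it without reaching the threshold
#'   is an error reporting the best R-squared achieved.
#' @return An object of class `poly_approx` with `coefficients` (ascending
#'   degree), `degree`, `r_squared` and `domain`.
#' @export
approximate_mean_polynomial <- function(curve, domain, r2_threshold = 0.995,
                                        step = 0.1, max_degree = 10) {
  if (r2_threshold <= 0 || r2_threshold >= 1) {
    stop("'r2_threshold' must lie in (0, 1)", call. = FALSE)
  }
  if (step <= 0) stop("'step' must be positive", call. = FALSE)
  fn <- curve_function(curve)
  grid <- seq(domain[1], domain[2], by = step)
  if (grid[length(grid)] < domain[2]) grid <- c(grid, domain[2])
  v <- fn(grid)
  sst <- sum((v - mean(v))^2)
  best_r2 <- -Inf
  for (deg in seq_len(max_degree)) {
    X <- outer(grid, 0:deg, `^`)
    cf <- qr.coef(qr(X), v)
    res <- v - drop(X %*% cf)
    r2 <- if (sst == 0) 1 else 1 - sum(res^2) / sst
    if (r2 > best_r2) best_r2 <- r2
    if (r2 > r2_threshold) {
      return(structure(list(coefficients = unname(cf), degree = deg,
                            r_squared = r2, domain = as.numeric(domain)),
                       class = "poly_approx"))
    }
  }
  stop("no polynomial of degree <= ", max_degree, " reached R^2 > ",
       r2_threshold, " (best R^2 = ", format(best_r2, digits = 6), ")",
       call. = FALSE)
}

curve_function <- function(curve) {
  if (is.function(curve)) return(curve)
  if (inherits(curve, "trajectory_fit")) return(function(t) mean_curve(curve, t))
  if (inherits(curve, "smooth_fit") && !is.null(curve$evaluate)) {
    return(curve$evaluate)
  }
  stop("'curve' must be a function, trajectory_fit or smooth_fit", call. = FALSE)
}

#' Evaluate a polynomial approximation
#'
#' @param pa A `poly_approx`.
#' @param t Times within the (closed) domain; evaluation outside it is an
#'   error, never an extrapolation.
#' @return Numeric vector.
#' @export
eval_polynomial <- function(pa, t) {
  stopifnot(inherits(pa, "poly_approx"))
  eps <- 1e-8 * diff(pa$domain)
  if (any(t < pa$domain[1] - eps | t > pa$domain[2] + eps)) {
    stop("time(s) outside the polynomial domain [", pa$domain[1], ", ",
         pa$domain[2], "]", call. = FALSE)
  }
  drop(outer(t, seq_along(pa$coefficients) - 1, `^`) %*% pa$coefficients)
}

#' Assemble a computational function set
#'
#' Bundles the polynomial mean approximation with the error family, its shape
#' parameters and the variance model into a single exportable object: the
#' mean function, quantile function and stochastic sampler for one analyte
#' and period.
#'
#' @param analyte `"albumin"` or `"aag"`.
#' @param period `"pregnancy"` or `"postpartum"`.
#' @param mean_poly A [approximate_mean_polynomial()] result.
#' @param family `"normal"`, `"mixture2"`, `"two_piece"`, or `"none"` for
#'   mean-only sets (e.g. AAG, where only the central tendency is modelled).
#' @param shape Family shape block: `list(skew=)` for two-piece,
#'   `list(weight=, offsets=, scales=)` for the mixture, `NULL` otherwise.
#' @param variance Variance-model block as stored in a `trajectory_fit`
#'   (`kind`, `scales`, optional `breakpoint` / `log_scale_coef`).
#' @param provenance List of metadata (e.g. `fit_id`, `seed`); a `date` field
#'   is added on export.
#' @return An object of class `function_set`.
#' @export
computational_function_set <- function(analyte, period, mean_poly,
                                       family = "normal", shape = NULL,
                                       variance = list(kind = "constant",
                                                       scales = NA_real_),
                                       provenance = list()) {
  stopifnot(inherits(mean_poly, "poly_approx"))
  analyte <- match.arg(analyte, c("albumin", "aag"))
  period <- match.arg(period, c("pregnancy", "postpartum"))
  family <- match.arg(family, c("normal", "mixture2", "two_piece", "none"))
  if (family == "two_piece" && is.null(shape$skew)) {
    stop("two_piece function set needs shape$skew", call. = FALSE)
  }
  if (family == "mixture2" &&
      (is.null(shape$weight) || is.null(shape$offsets) || is.null(shape$scales))) {
    stop("mixture2 function set needs shape weight/offsets/scales", call. = FALSE)
  }
  structure(list(analyte = analyte, period = period, mean_poly = mean_poly,
                 family = family, shape = shape, variance = variance,
                 domain = mean_poly$domain, provenance = provenance),
            class = "function_set")
}

#' Build a function set from a fitted trajectory model
#'
#' @param fit A `trajectory_fit` (or, for mean-only sets, a `smooth_fit` with
#'   an evaluator).
#' @inheritParams computational_function_set
#' @inheritParams approximate_mean_polynomial
#' @param seed Seed recorded in the provenance block.
#' @return A `function_set`.
#' @export
build_function_set <- function(fit, analyte, period, r2_threshold = 0.995,
                               step = 0.1, seed = NA_integer_) {
  if (inherits(fit, "trajectory_fit")) {
    pa <- approximate_mean_polynomial(fit, fit$domain, r2_threshold, step)
    computational_function_set(
      analyte, period, pa, family = fit$family, shape = fit$shape,
      variance = fit$variance,
      provenance = list(fit_id = paste0(analyte, "_", period, "_", fit$family),
                        seed = seed))
  } else if (inherits(fit, "smooth_fit")) {
    pa <- approximate_mean_polynomial(fit, fit$domain, r2_threshold, step)
    computational_function_set(
      analyte, period, pa, family = "none", shape = NULL,
      variance = list(kind = "none"),
      provenance = list(fit_id = paste0(analyte, "_", period, "_mean_only"),
                        seed = seed))
  } else {
    stop("'fit' must be a trajectory_fit or smooth_fit", call. = FALSE)
  }
}

fs_sigma <- function(fs, t) {
  v <- fs$variance
  switch(v$kind,
         constant = rep(v$scales[1], length(t)),
         piecewise_constant = ifelse(t > v$breakpoint, v$scales[2], v$scales[1]),
         smooth_in_time = exp(v$log_scale_coef[1] + v$log_scale_coef[2] * t),
         none = rep(NA_real_, length(t)))
}

#' Evaluate the exported mean function
#'
#' @param fs A `function_set`.
#' @param t Times within the set's domain.
#' @return Mean concentration estimate(s).
#' @export
mean_function_eval <- function(fs, t) {
  stopifnot(inherits(fs, "function_set"))
  eval_polynomial(fs$mean_poly, t)
}

#' Evaluate the exported quantile function
#'
#' Converts the polynomial mean value at `t` to the family location
#' (inverting the family's mean formula; for the two-piece family this
#' subtracts the closed-form mean offset) and applies the family quantile at
#' the local scale and shape.
#'
#' @param fs A `function_set` with a distributional family.
#' @param t Times within the domain.
#' @param p A single probability in (0, 1).
#' @return Concentration quantile(s) at each time.
#' @export
quantile_function_eval <- function(fs, t, p) {
  stopifnot(inherits(fs, "function_set"))
  if (fs$family == "none") {
    stop("mean-only function set: no quantile function available", call. = FALSE)
  }
  if (length(p) != 1L || p <= 0 || p >= 1) {
    stop("'p' must be a single probability in (0, 1)", call. = FALSE)
  }
  m <- mean_function_eval(fs, t)
  switch(fs$family,
         normal = stats::qnorm(p, m, fs_sigma(fs, t)),
         two_piece = {
           sig <- fs_sigma(fs, t)
           qtp(p, m - tp_mean_shift(sig, fs$shape$skew), sig, fs$shape$skew)
         },
         mixture2 = m + qmix2(p, 0, fs$shape$weight, fs$shape$offsets,
                              fs$shape$scales))
}

#' Sample a virtual population
#'
#' Draws times from a configured time sampler and concentrations from the
#' local error distribution — the stochastic generator used to create virtual
#' populations for population PBPK simulation.
#'
#' @param fs A `function_set` with a distributional family.
#' @param n Number of individuals (>= 1).
#' @param time_sampler One of `list(kind = "uniform")` (uniform over the
#'   domain), `list(kind = "fixed", time = t0)`, or
#'   `list(kind = "empirical", times = <vector>)` (resampled with
#'   replacement).
#' @param seed Integer seed; the draw is fully reproducible.
#' @return Data frame with columns `time` and `concentration`.
#' @export
sample_virtual_population <- function(fs, n, time_sampler = list(kind = "uniform"),
                                      seed = 1) {
  stopifnot(inherits(fs, "function_set"))
  if (fs$family == "none") {
    stop("mean-only function set: no sampler available", call. = FALSE)
  }
  if (n < 1) stop("'n' must be >= 1", call. = FALSE)
  with_seed(seed, {
    t <- switch(time_sampler$kind,
      uniform = stats::runif(n, fs$domain[1], fs$domain[2]),
      fixed = {
        if (is.null(time_sampler$time)) stop("fixed sampler needs 'time'")
        rep(time_sampler$time, n)
      },
      empirical = {
        ts <- time_sampler$times
        ts <- ts[ts >= fs$domain[1] & ts <= fs$domain[2]]
        if (!length(ts)) stop("no empirical times inside the domain")
        sample(ts, n, replace = TRUE)
      },
      stop("unknown time sampler kind: ", time_sampler$kind))
    m <- mean_function_eval(fs, t)
    conc <- switch(fs$family,
      normal = stats::rnorm(n, m, fs_sigma(fs, t)),
      two_piece = {
        sig <- fs_sigma(fs, t)
        rtp(n, m - tp_mean_shift(sig, fs$shape$skew), sig, fs$shape$skew)
      },
      mixture2 = m + rmix2(n, 0, fs$shape$weight, fs$shape$offsets,
                           fs$shape$scales))
    data.frame(time = t, concentration = conc)
  })
}

## ---- JSON bundle ---------------------------------------------------------

BUNDLE_SCHEMA_VERSION <- "1.0"

#' Export / import a function bundle as JSON
#'
#' The bundle is a schema-versioned JSON document carrying the polynomial
#' mean coefficients, family, shape, variance model, domain and provenance —
#' a neutral exchange format for PBPK platforms. Round-tripping a bundle
#' reproduces all evaluations exactly.
#'
#' @param fs A `function_set`.
#' @param path Optional file path; if `NULL`, the JSON string is returned.
#' @return `export_function_bundle`: the JSON string (invisibly, if written
#'   to a file). `import_function_bundle`: the reconstructed `function_set`.
#' @export
export_function_bundle <- function(fs, path = NULL) {
  stopifnot(inherits(fs, "function_set"))
  prov <- fs$provenance
  if (is.null(prov$date)) prov$date <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  doc <- list(
    schema_version = BUNDLE_SCHEMA_VERSION,
    analyte = fs$analyte, period = fs$period,
    domain = fs$domain,
    mean_polynomial = list(coefficients = fs$mean_poly$coefficients,
                           degree = fs$mean_poly$degree,
                           r_squared = fs$mean_poly$r_squared),
    family = fs$family,
    shape = fs$shape,
    variance_model = fs$variance,
    provenance = prov)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null",
                           pretty = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(as.character(json))
}

#' @rdname export_function_bundle
#' @param json A JSON string or path to a JSON file.
#' @export
import_function_bundle <- function(json) {
  txt <- if (length(json) == 1L && file.exists(json)) {
    paste(readLines(json, warn = FALSE), collapse = "\n")
  } else {
    paste(json, collapse = "\n")
  }
  doc <- jsonlite::fromJSON(txt, simplifyVector = TRUE)
  need <- function(path) {
    node <- doc
    for (nm in strsplit(path, ".", fixed = TRUE)[[1]]) {
      node <- node[[nm]]
      if (is.null(node)) {
        stop("function bundle is missing required field '", path, "'",
             call. = FALSE)
      }
    }
    node
  }
  ver <- need("schema_version")
  if (!identical(ver, BUNDLE_SCHEMA_VERSION)) {
    stop("unsupported bundle schema version: ", ver, call. = FALSE)
  }
  mp <- structure(list(coefficients = as.numeric(need("mean_polynomial.coefficients")),
                       degree = as.integer(need("mean_polynomial.degree")),
                       r_squared = as.numeric(need("mean_polynomial.r_squared")),
                       domain = as.numeric(need("domain"))),
                  class = "poly_approx")
  family <- need("family")
  shape <- doc$shape
  if (!is.null(shape)) shape <- lapply(shape, unlist, use.names = FALSE)
  variance <- need("variance_model")
  variance <- lapply(variance, function(x) if (is.list(x)) unlist(x) else x)
  if (family != "none" && family != "mixture2" && is.null(variance$scales) &&
      is.null(variance$log_scale_coef)) {
    stop("function bundle is missing required field 'variance_model.scales'",
         call. = FALSE)
  }
  computational_function_set(need("analyte"), need("period"), mp,
                             family = family, shape = shape,
                             variance = variance,
                             provenance = as.list(doc$provenance))
}
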