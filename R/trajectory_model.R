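#' Longitudinal observation sets
#'
#' Validates and tags a data frame of longitudinal analyte concentrations.
#' Required columns: `subject_id`, `analyte` (`"albumin"` or `"aag"`),
#' `period` (`"pregnancy"` or `"postpartum"`), `time` (weeks; gestational age
#' for pregnancy, weeks since delivery for postpartum, with 0 = delivery) and
#' `concentration` (g/L for albumin, mg/dL for AAG). Concentrations must be
#' positive and pregnancy times must lie in [20, 43] weeks (protocol
#' eligibility).
#'
#' @param df A data frame with the columns above.
#' @return The validated data frame with class `observation_set`.
#' @export
observation_set <- function(df) {
  req <- c("subject_id", "analyte", "period", "time", "concentration")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df)[req]
  if (!all(df$analyte %in% c("albumin", "aag"))) {
    stop("'analyte' must be \"albumin\" or \"aag\"", call. = FALSE)
  }
  if (!all(df$period %in% c("pregnancy", "postpartum"))) {
    stop("'period' must be \"pregnancy\" or \"postpartum\"", call. = FALSE)
  }
  if (any(!is.finite(df$time)) || any(df$time < 0)) {
    stop("'time' must be finite and nonnegative (weeks)", call. = FALSE)
  }
  if (any(!is.finite(df$concentration)) || any(df$concentration <= 0)) {
    stop("'concentration' must be finite and positive", call. = FALSE)
  }
  preg <- df$period == "pregnancy"
  if (any(preg & (df$time < 20 | df$time > 43))) {
    stop("pregnancy times must lie in [20, 43] weeks gestation", call. = FALSE)
  }
  class(df) <- c("observation_set", "data.frame")
  df
}

#' Variance models for the error scale
#'
#' The error scale sigma(t) is either constant, piecewise constant with a
#' single breakpoint (e.g. different scatter up to and beyond 0.5 weeks
#' postpartum), or log-linear in time (`smooth_in_time`).
#'
#' @param kind One of `"constant"`, `"piecewise_constant"`, `"smooth_in_time"`.
#' @param breakpoint Breakpoint in weeks (required for `piecewise_constant`).
#' @return An object of class `variance_model`.
#' @export
variance_model <- function(kind = c("constant", "piecewise_constant",
                                    "smooth_in_time"),
                           breakpoint = NULL) {
  kind <- match.arg(kind)
  if (kind == "piecewise_constant") {
    if (is.null(breakpoint) || !is.finite(breakpoint)) {
      stop("piecewise_constant variance needs a finite 'breakpoint' (weeks)",
           call. = FALSE)
    }
  } else {
    breakpoint <- NULL
  }
  structure(list(kind = kind, breakpoint = breakpoint),
            class = "variance_model")
}

#' Candidate model specification
#'
#' Combines an error family, a location smoother configuration and a variance
#' model. The mixture family is supported with constant error variance only;
#' the normal and two-piece families support all three variance models.
#'
#' @param family `"normal"`, `"mixture2"` or `"two_piece"`.
#' @param variance A [variance_model].
#' @param basis Optional [basis_spec] for the location smoother; defaults to
#'   20 equally spaced interior knots, cubic, over the observed time range.
#' @param penalty_order Difference-penalty order for the location smoother.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family = c("normal", "mixture2", "two_piece"),
                       variance = variance_model("constant"),
                       basis = NULL, penalty_order = 2) {
  family <- match.arg(family)
  stopifnot(inherits(variance, "variance_model"))
  if (family == "mixture2" && variance$kind != "constant") {
    stop("the mixture2 family supports constant error variance only",
         call. = FALSE)
  }
  structure(list(family = family, variance = variance, basis = basis,
                 penalty_order = as.integer(penalty_order)),
            class = "model_spec")
}

## ---- internal helpers ----------------------------------------------------

# raw-weight penalized solve: min sum(w (y - Bc)^2) + c' lamP c
pwls_raw <- function(y, B, w, lamP) {
  BtW <- t(B * w)
  drop(solve(BtW %*% B + lamP, BtW %*% y))
}

sigma_from_tau <- function(vm, tau, t, floor) {
  s <- switch(vm$kind,
              constant = rep(exp(tau[1]), length(t)),
              piecewise_constant = exp(tau[1] + tau[2] * (t > vm$breakpoint)),
              smooth_in_time = exp(tau[1] + tau[2] * t))
  pmax(s, floor)
}

traj_loglik <- function(family, y, f, sig, shape) {
  switch(family,
         normal = sum(stats::dnorm(y, f, sig, log = TRUE)),
         two_piece = sum(log(dtp(y, f, sig, shape$skew))),
         mixture2 = sum(log(dmix2(y, f, shape$weight, shape$offsets,
                                  shape$scales))))
}

## ---- fitting -------------------------------------------------------------

#' Fit a location-scale(-shape) trajectory model
#'
#' Fits a penalized B-spline location curve with one of three error families
#' by alternating (a) a penalized weighted update of the location spline
#' given the current scale/shape (for the mixture family, using
#' expectation-weighted responsibilities, i.e. an EM step) and (b) a
#' maximum-likelihood update of the scale and shape parameters given the
#' location curve. The penalized log-likelihood is nondecreasing across
#' iterations; the alternation stops when its relative change falls below
#' `tol` or after `max_iter` iterations (in which case the last iterate is
#' returned with `converged = FALSE`).
#'
#' The smoothing weight `lambda` for the location spline is chosen once by
#' generalized AIC on a preliminary normal fit (unless supplied) and then
#' held fixed during the alternation.
#'
#' For the two-piece family the spline models the split point (mode) of the
#' distribution; the reported arithmetic-mean curve ([mean_curve()]) adds the
#' closed-form mean offset, so it always equals the mean of the local error
#' distribution.
#'
#' @param data An [observation_set] (single analyte and period) or a data
#'   frame with `time` and `concentration` columns; at least 30 observations.
#' @param spec A [model_spec].
#' @param lambda Optional fixed smoothing weight; selected by GAIC if `NULL`.
#' @param k GAIC complexity penalty per effective degree of freedom.
#' @param max_iter,tol Iteration cap and relative log-likelihood tolerance.
#' @param n_restarts Number of EM initializations for the mixture family (the
#'   first is a deterministic residual split, the rest are random, seeded).
#' @param seed Seed for the mixture restarts.
#' @return An object of class `trajectory_fit` with the fitted location
#'   coefficients, variance model estimates, family shape estimates,
#'   `loglik`, `edf`, `gaic`, `converged` and the fitted time `domain`.
#' @export
fit_trajectory_model <- function(data, spec, lambda = NULL, k = 2,
                                 max_iter = 500, tol = 1e-8,
                                 n_restarts = 5, seed = 1) {
  stopifnot(inherits(spec, "model_spec"))
  if (all(c("analyte", "period") %in% names(data))) {
    if (length(unique(data$analyte)) > 1L || length(unique(data$period)) > 1L) {
      stop("data must contain a single analyte and period", call. = FALSE)
    }
  }
  t <- data$time
  y <- data$concentration
  n <- length(y)
  if (n < 30) {
    stop("insufficient data: need at least 30 observations, got ", n,
         call. = FALSE)
  }
  vm <- spec$variance
  if (vm$kind == "piecewise_constant" &&
      (vm$breakpoint <= min(t) || vm$breakpoint >= max(t))) {
    stop("variance breakpoint must lie inside the observed time range",
         call. = FALSE)
  }
  bs <- if (is.null(spec$basis)) basis_spec(min(t), max(t)) else spec$basis
  B <- build_basis(bs, t)
  K <- ncol(B)
  Pd <- diff_penalty(K, spec$penalty_order)

  # preliminary normal fit; fixes lambda and the penalty scale
  if (is.null(lambda)) {
    sel <- select_lambda_gaic(y, B, order = spec$penalty_order, k = k)
    lambda <- sel$penalty$lambda
    coef <- sel$fit$coefficients
  } else {
    coef <- fit_penalized_wls(y, B, penalty_spec(spec$penalty_order, lambda))$coefficients
  }
  f <- drop(B %*% coef)
  r <- y - f
  sd_y <- stats::sd(y)
  sfloor <- max(1e-6 * sd_y, 1e-8)
  s0 <- max(stats::sd(r), sfloor)
  lambda_star <- lambda / s0^2        # penalty on the log-likelihood scale
  lamP <- lambda_star * Pd

  pll <- function(coef, ll) ll - 0.5 * lambda_star *
    drop(crossprod(coef, Pd %*% coef))

  # --- initialize state ----------------------------------------------------
  state <- list()
  if (spec$family %in% c("normal", "two_piece")) {
    tau <- switch(vm$kind,
      constant = log(s0),
      piecewise_constant = {
        g <- t > vm$breakpoint
        s1 <- max(stats::sd(r[!g]), sfloor); s2 <- max(stats::sd(r[g]), sfloor)
        if (!is.finite(s1)) s1 <- s0
        if (!is.finite(s2)) s2 <- s0
        c(log(s1), log(s2) - log(s1))
      },
      smooth_in_time = c(log(s0), 0))
    state$tau <- tau
    if (spec$family == "two_piece") state$lnu <- 0
  }

  shape_of <- function(state) {
    switch(spec$family,
           normal = NULL,
           two_piece = list(skew = exp(state$lnu)),
           mixture2 = state$mix)
  }

  # one outer iteration; returns updated (coef, f, state)
  iterate <- function(coef, f, state, cur_pll) {
    if (spec$family == "normal") {
      sig <- sigma_from_tau(vm, state$tau, t, sfloor)
      coef <- pwls_raw(y, B, 1 / sig^2, lamP)
      f <- drop(B %*% coef)
      e <- y - f
      state$tau <- switch(vm$kind,
        constant = log(max(sqrt(mean(e^2)), sfloor)),
        piecewise_constant = {
          g <- t > vm$breakpoint
          s1 <- max(sqrt(mean(e[!g]^2)), sfloor)
          s2 <- max(sqrt(mean(e[g]^2)), sfloor)
          c(log(s1), log(s2) - log(s1))
        },
        smooth_in_time = {
          nll <- function(tau) {
            s <- sigma_from_tau(vm, tau, t, sfloor)
            -sum(stats::dnorm(y, f, s, log = TRUE))
          }
          stats::optim(state$tau, nll, method = "Nelder-Mead")$par
        })
    } else if (spec$family == "two_piece") {
      nu <- exp(state$lnu)
      sig <- sigma_from_tau(vm, state$tau, t, sfloor)
      e <- y - f
      w <- ifelse(e < 0, nu^2, 1 / nu^2) / sig^2
      cand <- pwls_raw(y, B, w, lamP)
      # step-halving keeps the penalized log-likelihood nondecreasing
      step <- 1
      repeat {
        ctry <- coef + step * (cand - coef)
        ftry <- drop(B %*% ctry)
        ll_try <- traj_loglik("two_piece", y, ftry, sig, list(skew = nu))
        if (is.finite(ll_try) && pll(ctry, ll_try) >= cur_pll - 1e-10) {
          coef <- ctry; f <- ftry
          break
        }
        step <- step / 2
        if (step < 1e-8) break
      }
      nll <- function(th) {
        tau <- th[-length(th)]
        s <- sigma_from_tau(vm, tau, t, sfloor)
        nu_ <- exp(min(max(th[length(th)], -1.8), 1.8))
        v <- -sum(log(dtp(y, f, s, nu_)))
        if (!is.finite(v)) 1e10 else v
      }
      opt <- stats::optim(c(state$tau, state$lnu), nll, method = "Nelder-Mead")
      state$tau <- opt$par[-length(opt$par)]
      state$lnu <- min(max(opt$par[length(opt$par)], -1.8), 1.8)
    } else { # mixture2
      m <- state$mix
      e <- y - f
      d1 <- stats::dnorm(e, m$offsets[1], m$scales[1]) * m$weight
      d2 <- stats::dnorm(e, m$offsets[2], m$scales[2]) * (1 - m$weight)
      gam <- d1 / pmax(d1 + d2, 1e-300)
      w <- gam / m$scales[1]^2 + (1 - gam) / m$scales[2]^2
      yt <- (gam * (y - m$offsets[1]) / m$scales[1]^2 +
               (1 - gam) * (y - m$offsets[2]) / m$scales[2]^2) / w
      coef <- pwls_raw(yt, B, w, lamP)
      f <- drop(B %*% coef)
      e <- y - f
      sg <- sum(gam)
      wt <- min(max(sg / n, 1e-6), 1 - 1e-6)
      o1 <- sum(gam * e) / max(sg, 1e-12)
      o2 <- sum((1 - gam) * e) / max(n - sg, 1e-12)
      s1 <- max(sqrt(sum(gam * (e - o1)^2) / max(sg, 1e-12)), sfloor)
      s2 <- max(sqrt(sum((1 - gam) * (e - o2)^2) / max(n - sg, 1e-12)), sfloor)
      # re-center so the location curve is the arithmetic mean
      delta <- wt * o1 + (1 - wt) * o2
      coef <- coef + delta
      f <- f + delta
      state$mix <- list(weight = wt, offsets = c(o1 - delta, o2 - delta),
                        scales = c(s1, s2))
    }
    sig <- if (spec$family == "mixture2") NULL
           else sigma_from_tau(vm, state$tau, t, sfloor)
    ll <- traj_loglik(spec$family, y, f, sig, shape_of(state))
    list(coef = coef, f = f, state = state, ll = ll,
         pll = pll(coef, ll))
  }

  run_loop <- function(coef, f, state, iters, tol) {
    sig <- if (spec$family == "mixture2") NULL
           else sigma_from_tau(vm, state$tau, t, sfloor)
    ll <- traj_loglik(spec$family, y, f, sig, shape_of(state))
    cur <- list(coef = coef, f = f, state = state, ll = ll,
                pll = pll(coef, ll))
    trace <- cur$pll
    converged <- FALSE
    for (it in seq_len(iters)) {
      nxt <- iterate(cur$coef, cur$f, cur$state, cur$pll)
      if (nxt$pll < cur$pll - 1e-6 * (1 + abs(cur$pll))) {
        warning("penalized log-likelihood decreased at iteration ", it,
                " (", format(cur$pll), " -> ", format(nxt$pll), ")")
      }
      done <- abs(nxt$pll - cur$pll) < tol * (1 + abs(cur$pll))
      cur <- nxt
      trace <- c(trace, cur$pll)
      if (done) { converged <- TRUE; break }
    }
    cur$trace <- trace
    cur$converged <- converged
    cur$iterations <- length(trace) - 1L
    cur
  }

  if (spec$family == "mixture2") {
    # seeded multi-start EM: deterministic residual split plus random starts
    starts <- list(as.numeric(r > stats::median(r)))
    if (n_restarts > 1) {
      extra <- with_seed(seed, lapply(seq_len(n_restarts - 1),
                                      function(i) stats::runif(n)))
      starts <- c(starts, extra)
    }
    best <- NULL
    for (g0 in starts) {
      wt <- min(max(mean(g0), 0.05), 0.95)
      o1 <- sum(g0 * r) / max(sum(g0), 1e-12)
      o2 <- sum((1 - g0) * r) / max(n - sum(g0), 1e-12)
      delta <- wt * o1 + (1 - wt) * o2
      st <- list(mix = list(weight = wt,
                            offsets = c(o1 - delta, o2 - delta),
                            scales = pmax(c(s0, s0), sfloor)))
      res <- run_loop(coef + delta, f + delta, st, iters = 40, tol = tol)
      if (is.null(best) || res$pll > best$pll) best <- res
    }
    cur <- run_loop(best$coef, best$f, best$state,
                    iters = max_iter, tol = tol)
  } else {
    cur <- run_loop(coef, f, state, iters = max_iter, tol = tol)
  }
  if (!cur$converged) {
    warning("trajectory model did not converge in ", max_iter,
            " iterations; returning last iterate")
  }

  # effective df: smoother trace at the final working weights + scale/shape
  final_w <- switch(spec$family,
    normal = 1 / sigma_from_tau(vm, cur$state$tau, t, sfloor)^2,
    two_piece = {
      nu <- exp(cur$state$lnu)
      sig <- sigma_from_tau(vm, cur$state$tau, t, sfloor)
      ifelse(y - cur$f < 0, nu^2, 1 / nu^2) / sig^2
    },
    mixture2 = {
      m <- cur$state$mix
      e <- y - cur$f
      d1 <- stats::dnorm(e, m$offsets[1], m$scales[1]) * m$weight
      d2 <- stats::dnorm(e, m$offsets[2], m$scales[2]) * (1 - m$weight)
      gam <- d1 / pmax(d1 + d2, 1e-300)
      gam / m$scales[1]^2 + (1 - gam) / m$scales[2]^2
    })
  BtW <- t(B * final_w)
  edf_spline <- sum(diag(solve(BtW %*% B + lamP, BtW %*% B)))
  n_extra <- switch(spec$family,
                    normal = 0, two_piece = 1, mixture2 = 4)
  n_sigma <- if (spec$family == "mixture2") 0
             else if (vm$kind == "constant") 1 else 2
  edf <- edf_spline + n_sigma + n_extra

  variance_est <- if (spec$family == "mixture2") {
    list(kind = "constant", scales = NULL)
  } else {
    tau <- cur$state$tau
    switch(vm$kind,
           constant = list(kind = vm$kind, scales = exp(tau[1])),
           piecewise_constant = list(kind = vm$kind,
                                     breakpoint = vm$breakpoint,
                                     scales = c(exp(tau[1]),
                                                exp(tau[1] + tau[2]))),
           smooth_in_time = list(kind = vm$kind, log_scale_coef = tau))
  }
  shape <- shape_of(cur$state)

  out <- list(spec = spec, family = spec$family,
              basis_spec = bs, penalty_order = spec$penalty_order,
              lambda = lambda, lambda_star = lambda_star,
              coefficients = cur$coef,
              variance = variance_est, shape = shape,
              loglik = cur$ll, edf = edf, edf_spline = edf_spline,
              k = k, gaic = -2 * cur$ll + k * edf,
              converged = cur$converged, iterations = cur$iterations,
              loglik_trace = cur$trace,
              domain = c(min(t), max(t)), n = n)
  class(out) <- "trajectory_fit"
  out
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat("<trajectory_fit> family =", x$family,
      "| variance =", x$variance$kind, "\n")
  cat("  n =", x$n, "| domain = [", x$domain[1], ",", x$domain[2], "] wks\n")
  cat("  loglik =", format(x$loglik, digits = 6),
      "| edf =", format(x$edf, digits = 4),
      "| GAIC(k=", x$k, ") =", format(x$gaic, digits = 6), "\n")
  if (!x$converged) cat("  NOT converged after", x$iterations, "iterations\n")
  invisible(x)
}

## ---- evaluation helpers --------------------------------------------------

check_domain <- function(fit, t) {
  eps <- 1e-8 * diff(fit$domain)
  if (any(t < fit$domain[1] - eps | t > fit$domain[2] + eps)) {
    stop("time(s) outside the fitted domain [", fit$domain[1], ", ",
         fit$domain[2], "]; the model does not extrapolate", call. = FALSE)
  }
  pmin(pmax(t, fit$domain[1]), fit$domain[2])
}

#' Fitted location and scale at given times
#'
#' `location_curve` evaluates the fitted location spline (the mode for the
#' two-piece family, the mean otherwise); `sigma_curve` evaluates the fitted
#' error scale; `mean_curve` evaluates the arithmetic mean of the local error
#' distribution (which for the two-piece family differs from the location by
#' the closed-form mean offset).
#'
#' @param fit A `trajectory_fit`.
#' @param t Times (weeks) inside the fitted domain.
#' @return Numeric vector of the same length as `t`.
#' @export
location_curve <- function(fit, t) {
  t <- check_domain(fit, t)
  drop(build_basis(fit$basis_spec, t) %*% fit$coefficients)
}

#' @rdname location_curve
#' @export
sigma_curve <- function(fit, t) {
  t <- check_domain(fit, t)
  v <- fit$variance
  if (fit$family == "mixture2") {
    m <- fit$shape
    s2 <- m$weight * (m$offsets[1]^2 + m$scales[1]^2) +
      (1 - m$weight) * (m$offsets[2]^2 + m$scales[2]^2)
    return(rep(sqrt(s2), length(t)))
  }
  switch(v$kind,
         constant = rep(v$scales, length(t)),
         piecewise_constant = ifelse(t > v$breakpoint, v$scales[2], v$scales[1]),
         smooth_in_time = exp(v$log_scale_coef[1] + v$log_scale_coef[2] * t))
}

#' @rdname location_curve
#' @export
mean_curve <- function(fit, t) {
  loc <- location_curve(fit, t)
  if (fit$family == "two_piece") {
    loc + tp_mean_shift(sigma_curve(fit, t), fit$shape$skew)
  } else {
    loc
  }
}

#' Local error distribution at one time point
#'
#' @param fit A `trajectory_fit`.
#' @param t A single time (weeks) inside the fitted domain.
#' @return A [dist_spec] for the model's error distribution at `t`.
#' @export
local_spec <- function(fit, t) {
  stopifnot(length(t) == 1L)
  loc <- location_curve(fit, t)
  switch(fit$family,
         normal = dist_normal(loc, sigma_curve(fit, t)),
         two_piece = dist_two_piece(loc, sigma_curve(fit, t), fit$shape$skew),
         mixture2 = dist_mixture2(loc, fit$shape$weight, fit$shape$offsets,
                                  fit$shape$scales))
}

# vectorized model quantile at observation times (one probability)
model_quantile_at <- function(fit, t, p) {
  loc <- location_curve(fit, t)
  switch(fit$family,
         normal = stats::qnorm(p, loc, sigma_curve(fit, t)),
         two_piece = qtp(p, loc, sigma_curve(fit, t), fit$shape$skew),
         mixture2 = loc + qmix2(p, 0, fit$shape$weight, fit$shape$offsets,
                                fit$shape$scales))
}

# vectorized model CDF at observation (time, value) pairs
model_cdf_at <- function(fit, t, y) {
  loc <- location_curve(fit, t)
  switch(fit$family,
         normal = stats::pnorm(y, loc, sigma_curve(fit, t)),
         two_piece = ptp(y, loc, sigma_curve(fit, t), fit$shape$skew),
         mixture2 = pmix2(y, loc, fit$shape$weight, fit$shape$offsets,
                          fit$shape$scales))
}

## ---- model comparison ----------------------------------------------------

#' Generalized AIC
#'
#' `-2 * loglik + k * edf` for any fitted model exposing `loglik` and `edf`.
#'
#' @param model A fitted model (e.g. a `trajectory_fit`).
#' @param k Complexity penalty per effective degree of freedom (default 2).
#' @return A single number.
#' @export
gaic <- function(model, k = 2) {
  if (is.null(model$loglik) || is.null(model$edf) ||
      !is.finite(model$loglik)) {
    stop("model must carry finite 'loglik' and 'edf'", call. = FALSE)
  }
  -2 * model$loglik + k * model$edf
}

#' Select among candidate models with a parsimony margin
#'
#' Candidates must be fits to the same data, ordered from simplest to most
#' complex. Walking up the complexity order, a more complex candidate
#' displaces the current choice only when its GAIC is lower by more than
#' `delta`; smaller improvements are treated as immaterial and the simpler
#' model is retained. The default margin (2.034) retains a constant-variance
#' model against a time-varying-variance alternative whose AIC is better by
#' exactly that amount.
#'
#' @param candidates A list of fitted models (simplest first).
#' @param delta Minimum GAIC improvement a more complex model must offer.
#' @param k GAIC complexity penalty.
#' @return The selected model, with attribute `"gaic_table"` summarizing all
#'   candidates.
#' @export
select_model <- function(candidates, delta = 2.034, k = 2) {
  if (!length(candidates)) stop("empty candidate list", call. = FALSE)
  g <- vapply(candidates, gaic, numeric(1), k = k)
  pick <- 1L
  for (j in seq_along(candidates)[-1]) {
    if (g[j] < g[pick] - delta) pick <- j
  }
  out <- candidates[[pick]]
  attr(out, "gaic_table") <- data.frame(
    candidate = seq_along(candidates),
    family = vapply(candidates, function(m) m$family %||% NA_character_,
                    character(1)),
    gaic = g, selected = seq_along(candidates) == pick)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- quantile curves, coverage, diagnostics ------------------------------

#' Time-dependent quantile curves
#'
#' Evaluates the family quantile at the local location/scale/shape over a
#' time grid. Curves are strictly ordered across probabilities at every grid
#' time.
#'
#' @param fit A `trajectory_fit`.
#' @param probs Probabilities in (0, 1), strictly increasing. The default is
#'   the 2.5th, 10th, 25th, 50th, 75th, 90th and 97.5th percentiles.
#' @param grid Time grid (weeks) inside the fitted domain.
#' @return A data frame with column `time` and one `q<percent>` column per
#'   probability; class `quantile_curve_set`.
#' @export
quantile_curves <- function(fit,
                            probs = c(0.025, 0.10, 0.25, 0.50, 0.75, 0.90, 0.975),
                            grid = seq(fit$domain[1], fit$domain[2],
                                       length.out = 101)) {
  if (any(diff(probs) <= 0) || any(probs <= 0) || any(probs >= 1)) {
    stop("'probs' must be strictly increasing within (0, 1)", call. = FALSE)
  }
  grid <- check_domain(fit, grid)
  qs <- vapply(probs, function(p) model_quantile_at(fit, grid, p),
               numeric(length(grid)))
  qs <- matrix(qs, nrow = length(grid))
  if (any(apply(qs, 1, function(r) any(diff(r) <= 0)))) {
    stop("quantile curves are not strictly ordered; degenerate fit")
  }
  out <- data.frame(time = grid, qs)
  names(out) <- c("time", paste0("q", format(100 * probs, trim = TRUE)))
  attr(out, "probs") <- probs
  class(out) <- c("quantile_curve_set", "data.frame")
  out
}

#' Quantile coverage concordance
#'
#' For each probability, the percentage of observations lying strictly below
#' the model quantile curve evaluated at their own time. A well calibrated
#' model gives observed percentages close to the nominal ones. Observations
#' exactly on a curve count as not-below.
#'
#' @param fit A `trajectory_fit`.
#' @param data Observations within the fitted domain.
#' @inheritParams quantile_curves
#' @return Data frame with columns `nominal` and `observed` (both percent).
#' @export
coverage_table <- function(fit, data,
                           probs = c(0.025, 0.10, 0.25, 0.50, 0.75, 0.90, 0.975)) {
  if (!nrow(as.data.frame(data))) stop("empty data", call. = FALSE)
  t <- data$time; y <- data$concentration
  obs <- vapply(probs, function(p) {
    100 * mean(y < model_quantile_at(fit, t, p))
  }, numeric(1))
  data.frame(nominal = 100 * probs, observed = obs)
}

#' Normalized quantile residual diagnostics
#'
#' Computes `r_i = qnorm(F(y_i | t_i))` under the fitted model. Under a
#' correctly specified model these are standard normal; the summary reports
#' their mean, variance and a QQ deviation statistic (maximum absolute
#' difference between the ordered residuals and the corresponding standard
#' normal quantiles). CDF values at machine 0 or 1 are clamped with a
#' warning.
#'
#' @inheritParams coverage_table
#' @return List with `residuals`, `mean`, `variance`, `qq_stat`, `n_clamped`.
#' @export
quantile_residual_diagnostics <- function(fit, data) {
  t <- data$time; y <- data$concentration
  u <- model_cdf_at(fit, t, y)
  eps <- 1e-12
  n_clamped <- sum(u <= eps | u >= 1 - eps)
  if (n_clamped > 0) {
    warning(n_clamped, " residual CDF value(s) at machine 0/1 were clamped")
  }
  u <- pmin(pmax(u, eps), 1 - eps)
  r <- stats::qnorm(u)
  n <- length(r)
  list(residuals = r, mean = mean(r), variance = stats::var(r),
       qq_stat = max(abs(sort(r) - stats::qnorm(stats::ppoints(n)))),
       n_clamped = n_clamped)
}

#' Exclude implausibly high concentrations
#'
#' Removes records with concentration strictly above `threshold` (default
#' 60 g/L, the rule used for serum albumin).
#'
#' @param data An [observation_set] or data frame with a `concentration`
#'   column.
#' @param threshold Positive concentration cutoff; `Inf` removes nothing.
#' @return List with `data` (filtered, same class) and `n_excluded`.
#' @export
exclude_outliers <- function(data, threshold = 60) {
  if (!is.finite(threshold) && !identical(threshold, Inf)) {
    stop("'threshold' must be positive", call. = FALSE)
  }
  if (threshold <= 0) stop("'threshold' must be positive", call. = FALSE)
  keep <- data$concentration <= threshold
  list(data = data[keep, , drop = FALSE], n_excluded = sum(!keep))
}

#' Plot a fitted trajectory with its quantile fan
#'
#' @param x A `trajectory_fit`.
#' @param data Optional observations to overlay.
#' @param probs Probabilities for the quantile fan.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.trajectory_fit <- function(x, data = NULL,
                                probs = c(0.025, 0.10, 0.25, 0.50, 0.75, 0.90, 0.975),
                                ...) {
  qc <- quantile_curves(x, probs)
  ylim <- range(qc[-1], if (!is.null(data)) data$concentration)
  graphics::plot(NA, xlim = x$domain, ylim = ylim,
                 xlab = "time (weeks)", ylab = "concentration", ...)
  if (!is.null(data)) {
    graphics::points(data$time, data$concentration, pch = 16,
                     col = grDevices::grey(0.4, 0.5))
  }
  for (j in seq_along(probs)) {
    graphics::lines(qc$time, qc[[j + 1]], lty = if (probs[j] == 0.5) 1 else 2)
  }
  invisible(x)
}
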