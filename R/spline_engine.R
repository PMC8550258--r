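#' B-spline basis specification
#'
#' Defines a B-spline basis on a closed time domain with equally spaced
#' interior knots. The default (20 interior knots, cubic) is a standard
#' P-spline configuration: rich enough that the difference penalty, not the
#' knot placement, controls smoothness.
#'
#' @param domain_lo,domain_hi Domain endpoints (weeks), `domain_lo < domain_hi`.
#' @param n_interior_knots Number of equally spaced interior knots (>= 1).
#' @param degree Spline degree (>= 1); 3 gives cubic B-splines.
#' @return An object of class `basis_spec`.
#' @export
basis_spec <- function(domain_lo, domain_hi, n_interior_knots = 20, degree = 3) {
  if (!is.finite(domain_lo) || !is.finite(domain_hi) || domain_lo >= domain_hi) {
    stop("need finite domain_lo < domain_hi", call. = FALSE)
  }
  if (n_interior_knots < 1) stop("'n_interior_knots' must be >= 1", call. = FALSE)
  if (degree < 1) stop("'degree' must be >= 1", call. = FALSE)
  structure(list(domain_lo = domain_lo, domain_hi = domain_hi,
                 n_interior_knots = as.integer(n_interior_knots),
                 degree = as.integer(degree)),
            class = "basis_spec")
}

#' Evaluate a B-spline design matrix
#'
#' Rows are a partition of unity (each row of nonnegative entries sums to 1)
#' and the matrix has `n_interior_knots + degree + 1` columns. Evaluation
#' outside the domain is an error; the smoothers in this package never
#' extrapolate.
#'
#' @param spec A [basis_spec].
#' @param times Numeric vector of evaluation times within the domain.
#' @return Design matrix with `length(times)` rows.
#' @export
build_basis <- function(spec, times) {
  stopifnot(inherits(spec, "basis_spec"))
  if (any(!is.finite(times))) stop("non-finite evaluation times", call. = FALSE)
  eps <- 1e-8 * (spec$domain_hi - spec$domain_lo)
  if (any(times < spec$domain_lo - eps | times > spec$domain_hi + eps)) {
    bad <- times[times < spec$domain_lo - eps | times > spec$domain_hi + eps]
    stop("time(s) outside the basis domain [", spec$domain_lo, ", ",
         spec$domain_hi, "]: ", paste(utils::head(signif(bad, 6), 5), collapse = ", "),
         call. = FALSE)
  }
  times <- pmin(pmax(times, spec$domain_lo), spec$domain_hi)
  ord <- spec$degree + 1L
  # equally spaced knots extended beyond the boundary (P-spline convention):
  # coefficients linear in index then reproduce linear functions of time, so
  # straight lines lie in the null space of the order-2 difference penalty
  h <- (spec$domain_hi - spec$domain_lo) / (spec$n_interior_knots + 1L)
  knots <- spec$domain_lo +
    h * ((-spec$degree):(spec$n_interior_knots + 1L + spec$degree))
  knots[spec$degree + spec$n_interior_knots + 2L] <- spec$domain_hi
  splines::splineDesign(knots, times, ord = ord)
}

#' Difference-penalty specification
#'
#' @param order Difference order of the penalty (>= 1); order 2 leaves linear
#'   trends unpenalized.
#' @param lambda Nonnegative smoothing weight.
#' @return An object of class `penalty_spec`.
#' @export
penalty_spec <- function(order = 2, lambda) {
  if (order < 1) stop("'order' must be >= 1", call. = FALSE)
  if (!is.finite(lambda) || lambda < 0) {
    stop("'lambda' must be nonnegative", call. = FALSE)
  }
  structure(list(order = as.integer(order), lambda = lambda),
            class = "penalty_spec")
}

# K x K difference-penalty matrix D'D of the given order
diff_penalty <- function(ncoef, order) {
  D <- diff(diag(ncoef), differences = order)
  crossprod(D)
}

#' Penalized weighted least squares on a B-spline basis
#'
#' Minimizes `sum(w * (y - B c)^2) + lambda * c' D'D c` with `D` the
#' difference matrix of the penalty order. Weights are normalized to mean 1
#' so the fit is invariant to uniform rescaling of the weights. The effective
#' degrees of freedom is the trace of the smoother (hat) matrix.
#'
#' @param y Numeric response vector.
#' @param basis Design matrix, as from [build_basis()].
#' @param penalty A [penalty_spec].
#' @param weights Optional nonnegative weights, recycled to `length(y)`.
#' @param basis_spec Optional [basis_spec]; if supplied, the returned fit
#'   carries an `evaluate(t)` closure over the domain.
#' @return An object of class `smooth_fit` with elements `coefficients`,
#'   `effective_df`, `fitted`, `rss`, `lambda`, `order`, `loglik` (Gaussian
#'   profile log-likelihood) and, when `basis_spec` is given, `evaluate`.
#' @export
fit_penalized_wls <- function(y, basis, penalty, weights = NULL,
                              basis_spec = NULL) {
  stopifnot(inherits(penalty, "penalty_spec"))
  basis <- as.matrix(basis)
  n <- length(y)
  if (nrow(basis) != n) stop("dimension mismatch between y and basis", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  weights <- rep_len(weights, n)
  if (any(weights < 0)) stop("weights must be nonnegative", call. = FALSE)
  w <- weights / mean(weights)
  K <- ncol(basis)
  if (penalty$lambda == 0) {
    r <- qr(sqrt(w) * basis)$rank
    if (r < K) {
      stop("rank-deficient design at lambda = 0: rank ", r, " < ", K,
           " columns; add data, reduce knots, or use lambda > 0",
           call. = FALSE)
    }
  }
  P <- diff_penalty(K, penalty$order)
  BtW <- t(basis * w)
  M <- BtW %*% basis + penalty$lambda * P
  coef <- drop(solve(M, BtW %*% y))
  fitted <- drop(basis %*% coef)
  edf <- sum(diag(solve(M, BtW %*% basis)))
  rss <- sum(w * (y - fitted)^2)
  s2 <- max(rss / n, 1e-300)
  ll <- -0.5 * n * (log(2 * pi * s2) + 1)
  out <- list(coefficients = coef, effective_df = edf, fitted = fitted,
              rss = rss, lambda = penalty$lambda, order = penalty$order,
              loglik = ll, basis_spec = basis_spec)
  if (!is.null(basis_spec)) {
    out$evaluate <- function(t) drop(build_basis(basis_spec, t) %*% coef)
  }
  class(out) <- "smooth_fit"
  out
}

#' @export
print.smooth_fit <- function(x, ...) {
  cat("<smooth_fit> ", length(x$coefficients), " coefficients, edf = ",
      format(x$effective_df, digits = 4), ", lambda = ",
      format(x$lambda, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Choose the smoothing weight by generalized AIC
#'
#' Scans a log-spaced grid of candidate `lambda` values, scoring each by
#' `-2 * loglik + k * edf` under a Gaussian working likelihood, then refines
#' around the grid winner by golden-section search in `log(lambda)`. Ties on
#' the grid go to the larger (smoother) `lambda`.
#'
#' @inheritParams fit_penalized_wls
#' @param order Difference-penalty order.
#' @param k GAIC complexity penalty per effective degree of freedom.
#' @param grid Candidate lambda grid (positive, increasing).
#' @return List with elements `penalty` (the selected [penalty_spec]), `fit`
#'   (the [fit_penalized_wls()] result at that lambda) and `gaic`.
#' @export
select_lambda_gaic <- function(y, basis, order = 2, weights = NULL, k = 2,
                               grid = 10^seq(-4, 8, length.out = 41),
                               basis_spec = NULL) {
  if (any(grid <= 0)) stop("lambda grid must be positive", call. = FALSE)
  grid <- sort(grid)
  score <- function(lam) {
    f <- fit_penalized_wls(y, basis, penalty_spec(order, lam), weights,
                           basis_spec = basis_spec)
    if (!is.finite(f$loglik)) stop("non-finite likelihood at lambda = ", lam,
                                   call. = FALSE)
    list(fit = f, gaic = -2 * f$loglik + k * f$effective_df)
  }
  best <- NULL; best_g <- Inf; best_i <- NA_integer_
  for (i in seq_along(grid)) {
    s <- score(grid[i])
    if (s$gaic <= best_g) {      # <=: larger lambda wins ties
      best <- s; best_g <- s$gaic; best_i <- i
    }
  }
  # one golden-section refinement between the grid neighbours of the winner
  lo <- log(grid[max(1L, best_i - 1L)])
  hi <- log(grid[min(length(grid), best_i + 1L)])
  if (hi > lo) {
    gr <- (sqrt(5) - 1) / 2
    a <- lo; b <- hi
    x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
    s1 <- score(exp(x1)); s2 <- score(exp(x2))
    for (it in 1:25) {
      if (s1$gaic < s2$gaic) {
        b <- x2; x2 <- x1; s2 <- s1
        x1 <- b - gr * (b - a); s1 <- score(exp(x1))
      } else {
        a <- x1; x1 <- x2; s1 <- s2
        x2 <- a + gr * (b - a); s2 <- score(exp(x2))
      }
      if (b - a < 1e-3) break
    }
    cand <- if (s1$gaic < s2$gaic) s1 else s2
    if (cand$gaic < best_g) best <- cand
  }
  list(penalty = penalty_spec(order, best$fit$lambda), fit = best$fit,
       gaic = -2 * best$fit$loglik + k * best$fit$effective_df)
}

#' Natural cubic smoothing spline with GCV
#'
#' Wrapper around [stats::smooth.spline()] choosing the smoothing parameter
#' by generalized cross-validation (or ordinary leave-one-out CV). Duplicate
#' time points are handled by within-time averaging with multiplicity
#' weights, as `smooth.spline` does internally. The returned evaluator
#' refuses to extrapolate beyond the observed time range.
#'
#' @param times,values Numeric vectors of equal length; at least 4 distinct
#'   time points are required.
#' @param cv `FALSE` (default) for GCV, `TRUE` for leave-one-out CV.
#' @return An object of class `smooth_fit` with `evaluate`, `effective_df`,
#'   `fitted` and `domain`.
#' @export
fit_cubic_smoothing_spline <- function(times, values, cv = FALSE) {
  if (length(times) != length(values)) stop("length mismatch", call. = FALSE)
  ok <- is.finite(times) & is.finite(values)
  times <- times[ok]; values <- values[ok]
  if (length(unique(times)) < 4L) {
    stop("need at least 4 distinct time points for a cubic smoothing spline",
         call. = FALSE)
  }
  ss <- stats::smooth.spline(times, values, cv = cv, keep.data = FALSE)
  dom <- range(times)
  evaluate <- function(t) {
    if (any(t < dom[1] - 1e-8 | t > dom[2] + 1e-8)) {
      stop("evaluation outside the fitted time range [", dom[1], ", ",
           dom[2], "]", call. = FALSE)
    }
    stats::predict(ss, pmin(pmax(t, dom[1]), dom[2]))$y
  }
  structure(list(coefficients = ss$fit$coef, effective_df = ss$df,
                 fitted = evaluate(times), evaluate = evaluate,
                 domain = dom, spline = ss),
            class = "smooth_fit")
}
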