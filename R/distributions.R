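#' Error-family specifications
#'
#' Constructors for the three error families used by the trajectory models:
#' a normal distribution, a two-component normal mixture constrained so that
#' its arithmetic mean equals `location`, and a two-piece ("split", skew
#' normal type 2) normal with side-dependent scaling.
#'
#' The mixture is parameterized by a shared `location` (its arithmetic mean)
#' plus component-mean offsets that satisfy the identifiability constraint
#' `weight * offsets[1] + (1 - weight) * offsets[2] = 0`, so that a location
#' curve fitted under this family is directly the mean curve.
#'
#' The two-piece density is
#' `f(y) = c * phi(nu * (y - mode) / scale)` for `y < mode` and
#' `f(y) = c * phi((y - mode) / (nu * scale))` for `y >= mode`, with
#' `c = 2 / (scale * (nu + 1/nu))` and `phi` the standard normal density.
#' `nu < 1` gives a heavier lower tail (negative skew); at `nu = 1` the
#' family reduces to `dist_normal(mode, scale)` exactly.
#'
#' @param location,mode Center of the distribution (analyte concentration
#'   units). For the two-piece family `mode` is the split point, not the mean.
#' @param scale,scales Positive scale parameter(s) in concentration units.
#' @param weight Mixing weight of the first component, in (0, 1).
#' @param offsets Length-2 numeric; component-mean deviations from `location`.
#' @param skew Positive skewness parameter `nu`; `skew < 1` means left skew.
#' @return An object of class `dist_spec` with elements `family` and `params`.
#' @examples
#' sp <- dist_two_piece(mode = 40, scale = 3.64, skew = 0.8)
#' dist_mean(sp)
#' dist_quantile(sp, c(0.025, 0.5, 0.975))
#' @name dist_spec
NULL

#' @rdname dist_spec
#' @export
dist_normal <- function(location, scale) {
  if (!is.finite(location)) stop("'location' must be finite", call. = FALSE)
  if (!is.finite(scale) || scale <= 0) {
    stop("'scale' must be a positive number", call. = FALSE)
  }
  structure(list(family = "normal",
                 params = list(location = location, scale = scale)),
            class = "dist_spec")
}

#' @rdname dist_spec
#' @export
dist_mixture2 <- function(location, weight, offsets, scales) {
  if (!is.finite(location)) stop("'location' must be finite", call. = FALSE)
  if (!is.finite(weight) || weight <= 0 || weight >= 1) {
    stop("'weight' must lie in the open interval (0, 1)", call. = FALSE)
  }
  if (length(offsets) != 2L || length(scales) != 2L) {
    stop("'offsets' and 'scales' must each have length 2", call. = FALSE)
  }
  if (any(!is.finite(scales)) || any(scales <= 0)) {
    stop("mixture 'scales' must be positive", call. = FALSE)
  }
  bal <- weight * offsets[1] + (1 - weight) * offsets[2]
  if (abs(bal) > 1e-8 * max(1, abs(offsets[1]), abs(offsets[2]))) {
    stop("mixture offsets violate the zero-weighted-mean constraint: ",
         "weight*offsets[1] + (1-weight)*offsets[2] = ", format(bal),
         call. = FALSE)
  }
  structure(list(family = "mixture2",
                 params = list(location = location, weight = weight,
                               offsets = as.numeric(offsets),
                               scales = as.numeric(scales))),
            class = "dist_spec")
}

#' @rdname dist_spec
#' @export
dist_two_piece <- function(mode, scale, skew) {
  if (!is.finite(mode)) stop("'mode' must be finite", call. = FALSE)
  if (!is.finite(scale) || scale <= 0) {
    stop("'scale' must be a positive number", call. = FALSE)
  }
  if (!is.finite(skew) || skew <= 0) {
    stop("'skew' must be a positive number", call. = FALSE)
  }
  structure(list(family = "two_piece",
                 params = list(mode = mode, scale = scale, skew = skew)),
            class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  cat("<dist_spec>", x$family, "\n")
  utils::str(x$params, give.attr = FALSE)
  invisible(x)
}

## ---- two-piece primitives (vectorized over y / p and over mode, scale) ----

dtp <- function(y, mode, scale, skew) {
  cc <- 2 / (scale * (skew + 1 / skew))
  z <- ifelse(y < mode, skew * (y - mode) / scale, (y - mode) / (skew * scale))
  cc * stats::dnorm(z)
}

ptp <- function(y, mode, scale, skew) {
  pl <- 1 / (skew^2 + 1)                       # mass below the mode
  ifelse(y < mode,
         2 * pl * stats::pnorm(skew * (y - mode) / scale),
         pl + (1 - pl) * (2 * stats::pnorm((y - mode) / (skew * scale)) - 1))
}

qtp <- function(p, mode, scale, skew) {
  n <- max(length(p), length(mode), length(scale), length(skew))
  p <- rep_len(p, n); mode <- rep_len(mode, n)
  scale <- rep_len(scale, n); skew <- rep_len(skew, n)
  pl <- 1 / (skew^2 + 1)
  out <- numeric(n)
  lo <- p <= pl
  out[lo] <- mode[lo] + (scale[lo] / skew[lo]) *
    stats::qnorm(p[lo] / (2 * pl[lo]))
  out[!lo] <- mode[!lo] + scale[!lo] * skew[!lo] *
    stats::qnorm(0.5 + (p[!lo] - pl[!lo]) / (2 * (1 - pl[!lo])))
  out
}

rtp <- function(n, mode, scale, skew) {
  pl <- 1 / (skew^2 + 1)
  left <- stats::runif(n) < pl
  z <- abs(stats::rnorm(n))
  ifelse(left, mode - (scale / skew) * z, mode + scale * skew * z)
}

# E[Y] - mode for a unit-mode two-piece distribution
tp_mean_shift <- function(scale, skew) {
  scale * sqrt(2 / pi) * (skew - 1 / skew)
}

## ---- mixture primitives (shape constant; location may be a vector) ----

dmix2 <- function(y, location, weight, offsets, scales) {
  weight * stats::dnorm(y, location + offsets[1], scales[1]) +
    (1 - weight) * stats::dnorm(y, location + offsets[2], scales[2])
}

pmix2 <- function(y, location, weight, offsets, scales) {
  weight * stats::pnorm(y, location + offsets[1], scales[1]) +
    (1 - weight) * stats::pnorm(y, location + offsets[2], scales[2])
}

# Bisection on the mixture CDF; tolerance 1e-10 in probability.
qmix2 <- function(p, location, weight, offsets, scales) {
  csd <- sqrt(weight * (offsets[1]^2 + scales[1]^2) +
                (1 - weight) * (offsets[2]^2 + scales[2]^2))
  vapply(p, function(pp) {
    lo <- location - 10 * csd
    hi <- location + 10 * csd
    while (pmix2(lo, location, weight, offsets, scales) > pp) lo <- lo - 10 * csd
    while (pmix2(hi, location, weight, offsets, scales) < pp) hi <- hi + 10 * csd
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      fm <- pmix2(mid, location, weight, offsets, scales)
      if (abs(fm - pp) < 1e-10 || (hi - lo) < 1e-13 * max(1, abs(mid))) {
        return(mid)
      }
      if (fm < pp) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
}

rmix2 <- function(n, location, weight, offsets, scales) {
  one <- stats::runif(n) < weight
  mu <- location + ifelse(one, offsets[1], offsets[2])
  sd <- ifelse(one, scales[1], scales[2])
  stats::rnorm(n, mu, sd)
}

## ---- generic interface --------------------------------------------------

#' Density, CDF, quantile, mean and sampler for an error family
#'
#' @param spec A [dist_spec] object.
#' @param y Numeric vector of concentrations.
#' @param p Numeric vector of probabilities in (0, 1).
#' @param n Number of draws (>= 1).
#' @param seed Integer seed; each call uses its own seed and leaves the
#'   global RNG stream untouched. `NULL` uses (and advances) the current
#'   stream.
#' @return `dist_density` and `dist_cdf` return numeric vectors the length of
#'   `y`; `dist_quantile` the length of `p`; `dist_mean` a single number;
#'   `dist_sample` a numeric vector of length `n`.
#' @examples
#' dist_cdf(dist_two_piece(0, 1, 0.8), 0)  # 1 / (0.8^2 + 1)
#' @export
dist_density <- function(spec, y) {
  stopifnot(inherits(spec, "dist_spec"))
  p <- spec$params
  switch(spec$family,
         normal = stats::dnorm(y, p$location, p$scale),
         mixture2 = dmix2(y, p$location, p$weight, p$offsets, p$scales),
         two_piece = dtp(y, p$mode, p$scale, p$skew))
}

#' @rdname dist_density
#' @export
dist_cdf <- function(spec, y) {
  stopifnot(inherits(spec, "dist_spec"))
  p <- spec$params
  switch(spec$family,
         normal = stats::pnorm(y, p$location, p$scale),
         mixture2 = pmix2(y, p$location, p$weight, p$offsets, p$scales),
         two_piece = ptp(y, p$mode, p$scale, p$skew))
}

#' @rdname dist_density
#' @export
dist_quantile <- function(spec, p) {
  stopifnot(inherits(spec, "dist_spec"))
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("probabilities must lie strictly between 0 and 1", call. = FALSE)
  }
  pr <- spec$params
  switch(spec$family,
         normal = stats::qnorm(p, pr$location, pr$scale),
         mixture2 = qmix2(p, pr$location, pr$weight, pr$offsets, pr$scales),
         two_piece = qtp(p, pr$mode, pr$scale, pr$skew))
}

#' @rdname dist_density
#' @export
dist_mean <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  p <- spec$params
  switch(spec$family,
         normal = p$location,
         mixture2 = p$location,          # forced by the offset constraint
         two_piece = p$mode + tp_mean_shift(p$scale, p$skew))
}

#' @rdname dist_density
#' @export
dist_sample <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "dist_spec"))
  if (length(n) != 1L || !is.finite(n) || n < 1) {
    stop("'n' must be a positive count", call. = FALSE)
  }
  p <- spec$params
  with_seed(seed, switch(spec$family,
    normal = stats::rnorm(n, p$location, p$scale),
    mixture2 = rmix2(n, p$location, p$weight, p$offsets, p$scales),
    two_piece = rtp(n, p$mode, p$scale, p$skew)))
}

# Evaluate an expression under a temporary RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  code
}
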