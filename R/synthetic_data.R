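#' Trajectory presets for synthetic data generation
#'
#' Each preset defines a "true" mean trajectory anchored at the reported
#' literature values, an error family with declared shape defaults, and a
#' variance model — the generating conditions for synthetic datasets that
#' mimic the longitudinal study the analysis methods target.
#'
#' Mean curves:
#' * `albumin_pregnancy`: linear through (20 wk, 34.3 g/L) and
#'   (37 wk, 33.4 g/L); domain 20-42 wk gestation.
#' * `albumin_postpartum`: exponential saturation
#'   `m(t) = 42.3 - 10.7 * exp(-k t)` with `k = log(10.7/4)/3` so that
#'   m(0) = 31.6, m(3) = 38.3 and the plateau is 42.3 g/L; domain 0-46 wk.
#' * `aag_pregnancy`: linear through (24 wk, 53.6) and (37 wk, 44.9) mg/dL;
#'   domain 24-38 wk.
#' * `aag_postpartum`: linear through (2 wk, 120.4) and (12 wk, 74.7) mg/dL;
#'   domain 2-13 wk.
#'
#' Noise models: the pregnancy albumin preset uses the two-component normal
#' mixture, the postpartum albumin preset the left-skewed two-piece family
#' with piecewise error SDs of 4.86 g/L up to 0.5 wk postpartum and 3.64 g/L
#' beyond, and the AAG presets a normal family. Shape values that are not
#' literature-reported (mixture weight/offsets/scales, the skew parameter,
#' the AAG SDs) are declared defaults and are flagged as such in the preset's
#' `not_from_literature` field.
#'
#' @param name One of `"albumin_pregnancy"`, `"albumin_postpartum"`,
#'   `"aag_pregnancy"`, `"aag_postpartum"`.
#' @return An object of class `trajectory_preset`.
#' @export
trajectory_preset <- function(name = c("albumin_pregnancy", "albumin_postpartum",
                                       "aag_pregnancy", "aag_postpartum")) {
  name <- match.arg(name)
  linfun <- function(t1, v1, t2, v2) {
    force(t1); force(v1); force(t2); force(v2)
    function(t) v1 + (v2 - v1) * (t - t1) / (t2 - t1)
  }
  p <- switch(name,
    albumin_pregnancy = list(
      analyte = "albumin", period = "pregnancy", domain = c(20, 42),
      mean_fn = linfun(20, 34.3, 37, 33.4),
      family = "mixture2",
      shape = list(weight = 0.8, offsets = c(0.9, -3.6), scales = c(2.5, 5.0)),
      variance = list(kind = "constant"),
      not_from_literature = c("weight", "offsets", "scales")),
    albumin_postpartum = {
      k <- log(10.7 / 4) / 3
      list(
        analyte = "albumin", period = "postpartum", domain = c(0, 46),
        mean_fn = function(t) 42.3 - 10.7 * exp(-k * t),
        family = "two_piece",
        shape = list(skew = 0.8),
        variance = list(kind = "piecewise_constant", breakpoint = 0.5,
                        scales = c(4.86, 3.64)),
        not_from_literature = "skew")
    },
    aag_pregnancy = list(
      analyte = "aag", period = "pregnancy", domain = c(24, 38),
      mean_fn = linfun(24, 53.6, 37, 44.9),
      family = "normal",
      shape = NULL,
      variance = list(kind = "constant", scales = 15),
      not_from_literature = "scales"),
    aag_postpartum = list(
      analyte = "aag", period = "postpartum", domain = c(2, 13),
      mean_fn = linfun(2, 120.4, 12, 74.7),
      family = "normal",
      shape = NULL,
      variance = list(kind = "constant", scales = 25),
      not_from_literature = "scales"))
  p$name <- name
  structure(p, class = "trajectory_preset")
}

#' Evaluate a preset's true mean trajectory
#'
#' @param preset A [trajectory_preset].
#' @param t Times within the preset domain.
#' @return Mean concentration(s).
#' @export
preset_mean <- function(preset, t) {
  stopifnot(inherits(preset, "trajectory_preset"))
  if (any(t < preset$domain[1] - 1e-8 | t > preset$domain[2] + 1e-8)) {
    stop("time(s) outside the preset domain [", preset$domain[1], ", ",
         preset$domain[2], "]", call. = FALSE)
  }
  preset$mean_fn(t)
}

#' Declared noise defaults for a preset
#'
#' Returns the preset's error-family parameter block together with a
#' `not_from_literature` marker naming every parameter whose value is a
#' declared default rather than a reported one.
#'
#' @param preset A [trajectory_preset].
#' @return List with `family`, `shape`, `variance` and `not_from_literature`.
#' @export
preset_noise_defaults <- function(preset) {
  stopifnot(inherits(preset, "trajectory_preset"))
  list(family = preset$family, shape = preset$shape,
       variance = preset$variance,
       not_from_literature = preset$not_from_literature)
}

preset_sigma <- function(preset, t) {
  v <- preset$variance
  switch(v$kind,
         constant = rep(v$scales[1], length(t)),
         piecewise_constant = ifelse(t > v$breakpoint, v$scales[2], v$scales[1]))
}

#' Longitudinal study designs
#'
#' Sampling structure for the synthetic generator: number of subjects,
#' per-subject sample-count distribution (the majority of subjects contribute
#' at most two samples), visit windows, and how many implausible high
#' outliers (> 60 g/L) to inject. `default_study_design()` returns the
#' design emulating the source study's structure for a preset:
#' 380 pregnant subjects yielding about 870 albumin samples with visits in
#' the 20-26 and 30-38 wk windows plus late-gestation draws; 354 postpartum
#' subjects (about 760 samples) with a delivery sample at t = 0, visits at
#' 2-24 wk and delayed visits up to 46 wk; 31 / 30 subjects for the sparse
#' AAG cohorts.
#'
#' @param n_subjects Number of subjects.
#' @param count_probs Named probabilities for 1, 2, ... samples per subject.
#' @param visit_windows List of `c(lo, hi)` windows (weeks); the i-th sample
#'   of a subject is drawn uniformly from window `min(i, length(windows))`.
#'   A degenerate window (`lo == hi`) gives a fixed time.
#' @param outlier_count Number of records replaced by > 60 g/L outliers.
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_subjects, count_probs, visit_windows,
                         outlier_count = 0) {
  if (n_subjects < 1) stop("'n_subjects' must be >= 1", call. = FALSE)
  if (abs(sum(count_probs) - 1) > 1e-8 || any(count_probs < 0)) {
    stop("'count_probs' must be nonnegative and sum to 1", call. = FALSE)
  }
  if (!length(visit_windows)) stop("need at least one visit window", call. = FALSE)
  for (w in visit_windows) {
    if (length(w) != 2L || w[1] > w[2]) {
      stop("each visit window must be c(lo, hi) with lo <= hi", call. = FALSE)
    }
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 count_probs = count_probs,
                 visit_windows = visit_windows,
                 outlier_count = as.integer(outlier_count)),
            class = "study_design")
}

#' @rdname study_design
#' @param preset A [trajectory_preset] (or its name).
#' @export
default_study_design <- function(preset) {
  name <- if (inherits(preset, "trajectory_preset")) preset$name else preset
  switch(name,
    albumin_pregnancy = study_design(
      n_subjects = 380,
      count_probs = c(`1` = 0.22, `2` = 0.48, `3` = 0.15, `4` = 0.15),
      visit_windows = list(c(20, 26), c(30, 38), c(37, 42), c(20, 42)),
      outlier_count = 1),
    albumin_postpartum = study_design(
      n_subjects = 354,
      count_probs = c(`1` = 0.26, `2` = 0.46, `3` = 0.16, `4` = 0.12),
      visit_windows = list(c(0, 0), c(2, 24), c(2, 24), c(24, 46)),
      outlier_count = 1),
    aag_pregnancy = study_design(
      n_subjects = 31,
      count_probs = c(`1` = 0.84, `2` = 0.16),
      visit_windows = list(c(24, 38), c(24, 38))),
    aag_postpartum = study_design(
      n_subjects = 30,
      count_probs = c(`1` = 0.94, `2` = 0.06),
      visit_windows = list(c(2, 13), c(2, 13))),
    stop("no default design for preset '", name, "'", call. = FALSE))
}

#' Generate a synthetic longitudinal dataset
#'
#' Per subject, draws a sample count from the design's count distribution and
#' visit times from the corresponding windows, then draws each concentration
#' from the preset's error family centred so that its arithmetic mean equals
#' the preset mean trajectory (for the two-piece family the mode is offset by
#' the closed-form mean shift; the piecewise error SD applies by visit time).
#' Finally the configured number of implausible outliers (uniform on
#' 61-70 g/L) is injected. Fully reproducible given `seed`.
#'
#' @param design A [study_design].
#' @param preset A [trajectory_preset].
#' @param seed Integer seed.
#' @return An [observation_set].
#' @export
generate_dataset <- function(design, preset, seed = 1) {
  stopifnot(inherits(design, "study_design"),
            inherits(preset, "trajectory_preset"))
  for (w in design$visit_windows) {
    if (w[1] < preset$domain[1] - 1e-8 || w[2] > preset$domain[2] + 1e-8) {
      stop("visit window [", w[1], ", ", w[2], "] lies outside the preset ",
           "domain [", preset$domain[1], ", ", preset$domain[2], "]",
           call. = FALSE)
    }
  }
  with_seed(seed, {
    counts <- sample(as.integer(names(design$count_probs)),
                     design$n_subjects, replace = TRUE,
                     prob = design$count_probs)
    subject <- rep(sprintf("S%04d", seq_len(design$n_subjects)), counts)
    visit_idx <- unlist(lapply(counts, seq_len), use.names = FALSE)
    nw <- length(design$visit_windows)
    t <- vapply(visit_idx, function(i) {
      w <- design$visit_windows[[min(i, nw)]]
      if (w[1] == w[2]) w[1] else stats::runif(1, w[1], w[2])
    }, numeric(1))
    n <- length(t)
    m <- preset_mean(preset, t)
    sig <- preset_sigma(preset, t)
    conc <- switch(preset$family,
      normal = stats::rnorm(n, m, sig),
      mixture2 = m + rmix2(n, 0, preset$shape$weight, preset$shape$offsets,
                           preset$shape$scales),
      two_piece = rtp(n, m - tp_mean_shift(sig, preset$shape$skew), sig,
                      preset$shape$skew))
    conc <- pmax(conc, 0.1)   # concentrations are physically positive
    if (design$outlier_count > 0) {
      idx <- sample(n, design$outlier_count)
      conc[idx] <- stats::runif(design$outlier_count, 61, 70)
    }
    observation_set(data.frame(subject_id = subject,
                               analyte = preset$analyte,
                               period = preset$period,
                               time = t, concentration = conc))
  })
}
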