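#' Reference equations for women without HIV infection
#'
#' Published reference equations (e.g. from PBPK platform publications)
#' describing plasma-protein concentrations against gestational age or
#' postpartum duration. Their coefficients are user-supplied configuration —
#' this package ships only the printed point evaluations as validation
#' fixtures (see [reference_anchors()]), never coefficient sets of its own.
#'
#' @param label Source tag (e.g. `"dallmann"`, `"abduljalil"`).
#' @param analyte,period As in [observation_set()].
#' @param type `"polynomial"` (coefficients in ascending degree over one
#'   domain) or `"piecewise"` (a list of segments, each
#'   `list(domain = c(lo, hi), coefficients = ...)`).
#' @param coefficients Ascending-degree coefficients (polynomial type).
#' @param pieces Segment list (piecewise type).
#' @param domain Length-2 time domain in weeks.
#' @param sd Optional dispersion (standard deviation, concentration units).
#' @return An object of class `reference_equation`.
#' @export
reference_equation <- function(label, analyte, period,
                               type = c("polynomial", "piecewise"),
                               coefficients = NULL, pieces = NULL,
                               domain = NULL, sd = NULL) {
  type <- match.arg(type)
  if (type == "polynomial") {
    if (is.null(coefficients) || is.null(domain)) {
      stop("polynomial reference equation needs coefficients and domain",
           call. = FALSE)
    }
  } else {
    if (is.null(pieces) || !length(pieces)) {
      stop("piecewise reference equation needs a nonempty 'pieces' list",
           call. = FALSE)
    }
    domain <- range(unlist(lapply(pieces, `[[`, "domain")))
  }
  if (!is.null(sd) && sd <= 0) stop("'sd' must be positive", call. = FALSE)
  structure(list(label = label, analyte = analyte, period = period,
                 type = type, coefficients = coefficients, pieces = pieces,
                 domain = as.numeric(domain), sd = sd),
            class = "reference_equation")
}

#' Evaluate a reference equation
#'
#' @param eq A [reference_equation].
#' @param t Times within the equation's domain.
#' @return Concentration estimate(s).
#' @export
evaluate_reference <- function(eq, t) {
  stopifnot(inherits(eq, "reference_equation"))
  eps <- 1e-8 * diff(eq$domain)
  if (any(t < eq$domain[1] - eps | t > eq$domain[2] + eps)) {
    stop("time(s) outside the reference-equation domain [", eq$domain[1],
         ", ", eq$domain[2], "]", call. = FALSE)
  }
  polyval <- function(cf, x) drop(outer(x, seq_along(cf) - 1, `^`) %*% cf)
  if (eq$type == "polynomial") return(polyval(eq$coefficients, t))
  vapply(t, function(tt) {
    for (i in seq_along(eq$pieces)) {
      pc <- eq$pieces[[i]]
      last <- i == length(eq$pieces)
      if (tt >= pc$domain[1] - eps &&
          (tt < pc$domain[2] || (last && tt <= pc$domain[2] + eps))) {
        return(polyval(pc$coefficients, tt))
      }
    }
    stop("no piece covers t = ", tt, call. = FALSE)
  }, numeric(1))
}

#' Printed reference anchor values
#'
#' Point evaluations of the published reference equations, as printed in the
#' source literature, used to validate user-supplied reference-equation
#' configurations. These are pure data; the package never reconstructs the
#' underlying coefficient sets.
#'
#' @return Data frame with columns `source`, `analyte`, `period`, `time`
#'   (weeks) and `value` (g/L for albumin, mg/dL for AAG).
#' @export
reference_anchors <- function() {
  path <- system.file("extdata", "reference_anchors.csv", package = "periprot",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Validate a reference-equation configuration against printed anchors
#'
#' Evaluates each supplied equation at the anchor times for its source /
#' analyte / period and compares with the printed values.
#'
#' @param eqs A list of [reference_equation]s.
#' @param anchors Anchor table, by default [reference_anchors()].
#' @param tol Absolute tolerance in concentration units.
#' @return Data frame with one row per matched anchor and a logical `pass`
#'   column; anchors with no matching equation are omitted with a message.
#' @export
validate_reference_config <- function(eqs, anchors = reference_anchors(),
                                      tol = 0.05) {
  keys <- vapply(eqs, function(e) paste(e$label, e$analyte, e$period, sep = "/"),
                 character(1))
  rows <- list()
  for (i in seq_len(nrow(anchors))) {
    a <- anchors[i, ]
    j <- match(paste(a$source, a$analyte, a$period, sep = "/"), keys)
    if (is.na(j)) next
    got <- evaluate_reference(eqs[[j]], a$time)
    rows[[length(rows) + 1L]] <- data.frame(
      source = a$source, analyte = a$analyte, period = a$period,
      time = a$time, printed = a$value, evaluated = got,
      pass = abs(got - a$value) <= tol)
  }
  if (!length(rows)) {
    message("no supplied reference equation matches any printed anchor; ",
            "nothing validated")
    return(data.frame())
  }
  do.call(rbind, rows)
}

#' Tail probabilities for a normal concentration model
#'
#' `tail_probability_analytic` returns `1 - pnorm((threshold - mean)/sd)` as
#' a probability; `tail_probability_mc` estimates the same quantity by seeded
#' Monte-Carlo simulation and reports a percentage, mirroring the
#' simulation-based distributional comparisons used when contrasting fitted
#' models with reference equations.
#'
#' @param mean,sd Normal mean and standard deviation (concentration units).
#' @param threshold Concentration threshold.
#' @param n Number of simulation draws.
#' @param seed Integer seed.
#' @return `tail_probability_analytic`: probability in `[0, 1]`.
#'   `tail_probability_mc`: percentage in `[0, 100]`.
#' @examples
#' tail_probability_analytic(34.8, 5.33, 40)       # 0.1646
#' tail_probability_mc(34.8, 5.33, 40, seed = 1)   # about 16.5
#' @export
tail_probability_analytic <- function(mean, sd, threshold) {
  if (sd <= 0) stop("'sd' must be positive", call. = FALSE)
  1 - stats::pnorm((threshold - mean) / sd)
}

#' @rdname tail_probability_analytic
#' @export
tail_probability_mc <- function(mean, sd, threshold, n = 10000, seed = 1) {
  if (sd <= 0) stop("'sd' must be positive", call. = FALSE)
  if (n < 1) stop("'n' must be >= 1", call. = FALSE)
  draws <- with_seed(seed, stats::rnorm(n, mean, sd))
  100 * sum(draws > threshold) / n
}

#' Percent of a plateau value
#'
#' `100 * value / plateau`, the convention used to express e.g. the albumin
#' concentration at delivery relative to its eventual postpartum plateau.
#'
#' @param value Concentration.
#' @param plateau Positive plateau concentration.
#' @return Percentage.
#' @examples
#' round(percent_of_plateau(31.6, 42.3))  # 75
#' @export
percent_of_plateau <- function(value, plateau) {
  if (any(plateau <= 0)) stop("'plateau' must be positive", call. = FALSE)
  100 * value / plateau
}
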