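# Growth-rate calibration: an exponential model linking cytoplasmic
# ribosome density x (per 0.1 fl) to population doubling time y (min),
#   y = a * exp(-b * x).
# Cells of fast-growing species pack more ribosomes per unit cytoplasm, so
# doubling time decays with density. The model allows a doubling-time
# estimate for organisms whose density is measurable by structome analysis
# but which cannot be grown in culture.

#' Construct a doubling-time calibration model
#'
#' @param a doubling time at zero ribosome density, min; must be positive.
#' @param b decay rate per unit density (per ribosomes/0.1 fl); must be
#'   positive (doubling time decreases with density).
#' @param provenance free-text note on where the parameters come from.
#' @return an object of class `"doubling_model"`.
#' @seealso [structome_calibration()] for the reference parameterisation,
#'   [fit_doubling_model()] to estimate (a, b) from data.
#' @export
doubling_model <- function(a, b, provenance = "user-supplied") {
  stopifnot_scalar_number(a, "a", 0, strict = TRUE)
  stopifnot_scalar_number(b, "b", 0, strict = TRUE)
  structure(list(a = a, b = b, provenance = as.character(provenance)),
            class = "doubling_model")
}

#' Reference ribosome-density calibration
#'
#' The published reference parameterisation, y = 4998.5 * exp(-0.002 x),
#' anchored on species with known doubling times and structome-measured
#' ribosome densities (*E. coli*, *S. cerevisiae*, *M. tuberculosis*).
#'
#' @return a [doubling_model()] with a = 4998.5 min, b = 0.002.
#' @export
#' @examples
#' predict_doubling_time(2840, structome_calibration())  # E. coli, ~17 min
structome_calibration <- function() {
  doubling_model(4998.5, 0.002,
                 provenance = "reference fit to known doubling times")
}

#' @export
print.doubling_model <- function(x, ...) {
  cat(sprintf("Doubling-time calibration: y = %.6g * exp(-%.6g * x)\n",
              x$a, x$b))
  cat("  x: ribosome density per 0.1 fl cytoplasm; y: doubling time (min)\n")
  cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
coef.doubling_model <- function(object, ...) {
  c(a = object$a, b = object$b)
}

#' Predict doubling time from ribosome density
#'
#' @param density ribosome density, count per 0.1 fl cytoplasm; >= 0.
#' @param model a [doubling_model()]; defaults to the reference
#'   calibration.
#' @return predicted doubling time(s), min.
#' @export
predict_doubling_time <- function(density, model = structome_calibration()) {
  stopifnot(inherits(model, "doubling_model"))
  if (any(!is.finite(density)) || any(density < 0)) {
    stop("'density' must be finite and non-negative", call. = FALSE)
  }
  model$a * exp(-model$b * density)
}

#' @export
predict.doubling_model <- function(object, density, ...) {
  predict_doubling_time(density, object)
}

#' Fit the exponential calibration to (density, doubling time) pairs
#'
#' Log-linear least squares: regresses `log(doubling_time)` on `density`
#' with [stats::lm()] and maps the coefficients back, a = exp(intercept),
#' b = -slope. With exactly two distinct points the fit interpolates them
#' exactly.
#'
#' @param density ribosome densities, per 0.1 fl; at least two distinct
#'   values.
#' @param doubling_time doubling times, min; all positive.
#' @param provenance note stored in the fitted model.
#' @return a [doubling_model()] carrying the fitted `lm` in `$fit`.
#' @export
fit_doubling_model <- function(density, doubling_time,
                               provenance = "log-linear least squares fit") {
  if (length(density) != length(doubling_time) || length(density) < 2) {
    stop("need at least 2 (density, doubling_time) pairs", call. = FALSE)
  }
  if (any(!is.finite(density)) || any(!is.finite(doubling_time))) {
    stop("pairs must be finite", call. = FALSE)
  }
  if (any(doubling_time <= 0)) {
    stop("doubling times must be positive", call. = FALSE)
  }
  if (length(unique(density)) < 2) {
    stop("densities are rank deficient: need at least 2 distinct values",
         call. = FALSE)
  }
  fit <- stats::lm(log(doubling_time) ~ density)
  a <- exp(unname(stats::coef(fit)[1]))
  b <- -unname(stats::coef(fit)[2])
  if (b <= 0) {
    stop("fitted decay rate is not positive: doubling time does not ",
         "decrease with density in these data", call. = FALSE)
  }
  model <- doubling_model(a, b, provenance = provenance)
  model$fit <- fit
  model
}

#' Invert the calibration: density from doubling time
#'
#' Algebraic inverse of [predict_doubling_time()]: `x = log(a / y) / b`.
#' Only defined for `0 < y <= a` (longer doubling times would imply a
#' negative density).
#'
#' @param doubling_time doubling time, min.
#' @param model a [doubling_model()].
#' @return ribosome density, per 0.1 fl cytoplasm.
#' @export
invert_doubling <- function(doubling_time, model = structome_calibration()) {
  stopifnot(inherits(model, "doubling_model"))
  if (any(!is.finite(doubling_time)) || any(doubling_time <= 0)) {
    stop("'doubling_time' must be positive and finite", call. = FALSE)
  }
  if (any(doubling_time > model$a)) {
    stop("'doubling_time' exceeds the model's zero-density intercept; ",
         "the implied density would be negative", call. = FALSE)
  }
  log(model$a / doubling_time) / model$b
}
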