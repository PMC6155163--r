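#' Temperature (environmental) response function
#'
#' A tolerance envelope mapping an environmental driver (here sea-surface
#' temperature) to a multiplier in [0, 1] on a group's foraging capacity.
#' It is anchored by four temperatures: absolute minimum and maximum
#' tolerances, and the 10th/90th preferable quantiles between which the
#' multiplier is 1. The shoulders are linear (a trapezoid), the minimal
#' continuous shape through the four anchors; `shape = "step"` degenerates
#' both shoulders to steps.
#'
#' @param min,q10,q90,max anchor temperatures (degrees C), with
#'   `min <= q10 <= q90 <= max` and `min < max`.
#' @param shape `"trapezoid"` (default) or `"step"`.
#' @return An object of class `env_response`.
#' @export
env_response <- function(min, q10, q90, max, shape = c("trapezoid", "step")) {
  shape <- match.arg(shape)
  if (!(min <= q10 && q10 <= q90 && q90 <= max)) {
    stop("env_response anchors must satisfy min <= q10 <= q90 <= max")
  }
  if (!(min < max)) stop("env_response requires min < max")
  structure(list(min = min, q10 = q10, q90 = q90, max = max, shape = shape),
            class = "env_response")
}

#' @export
print.env_response <- function(x, ...) {
  cat(sprintf("env_response (%s): min %.2f | q10 %.2f | q90 %.2f | max %.2f degC\n",
              x$shape, x$min, x$q10, x$q90, x$max))
  invisible(x)
}

#' Foraging-capacity multiplier at a driver value
#'
#' Returns 1 inside the preferable range `[q10, q90]`, 0 at or beyond the
#' tolerance limits, and interpolates linearly on the shoulders. A degenerate
#' shoulder (`min == q10` or `q90 == max`) acts as a step.
#'
#' @param resp an [env_response()].
#' @param x driver value(s), degrees C.
#' @return numeric vector of multipliers in [0, 1], same length as `x`.
#' @examples
#' r <- env_response(10, 15, 25, 30)
#' response_multiplier(r, c(12.5, 20, 35))   # 0.5, 1, 0
#' @export
response_multiplier <- function(resp, x) {
  stopifnot(inherits(resp, "env_response"))
  f <- numeric(length(x))
  inside <- x >= resp$q10 & x <= resp$q90
  f[inside] <- 1
  lo <- x > resp$min & x < resp$q10
  if (any(lo)) {
    f[lo] <- if (resp$shape == "step" || resp$q10 == resp$min) 1 else
      (x[lo] - resp$min) / (resp$q10 - resp$min)
  }
  hi <- x > resp$q90 & x < resp$max
  if (any(hi)) {
    f[hi] <- if (resp$shape == "step" || resp$max == resp$q90) 1 else
      (resp$max - x[hi]) / (resp$max - resp$q90)
  }
  f
}

#' Apply a response function along a driver time series
#'
#' @param resp an [env_response()].
#' @param driver numeric vector of driver values; no missing values allowed
#'   (no imputation is performed).
#' @return numeric vector of multipliers, same length and names as `driver`.
#' @export
multiplier_series <- function(resp, driver) {
  if (anyNA(driver)) stop("driver series contains missing values")
  out <- response_multiplier(resp, as.numeric(driver))
  names(out) <- names(driver)
  out
}
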