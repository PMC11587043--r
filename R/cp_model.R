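#' Fit the two-parameter critical power model
#'
#' Fits the hyperbolic power-duration relationship `P = CP + W'/t` to a set
#' of (power, duration) points.  The primary parameterisation
#' (`method = "inverse_time"`) is the linearised power-1/time form:
#' ordinary least squares of power on reciprocal duration, whose intercept
#' is CP (W) and slope is W' (J).  The equivalent work-time form
#' (`method = "work_time"`, regressing total work `P * t` on `t`; slope CP,
#' intercept W') is provided as a cross-check and agrees on
#' well-conditioned data.
#'
#' Points are unweighted.  A fit with non-positive CP or W' is returned
#' with a warning rather than rejected.
#'
#' @param power Power outputs (W), one per exhaustive trial.
#' @param duration Times to exhaustion (s), positive and distinct.
#' @param method `"inverse_time"` (primary) or `"work_time"`.
#' @return An object of class `cpfit`: list with `cp`, `w_prime`,
#'   `r_squared`, `se_cp`, `se_w_prime`, `n_points`, `method`, the
#'   underlying `lm` fit and the input `data`.
#' @examples
#' fit <- critical_power(c(450, 350, 290, 270), c(60, 120, 300, 600))
#' coef(fit)           # cp = 250 W, w_prime = 12000 J
#' predict(fit, duration = 240)
#' @seealso [prescribe_power()], [predicted_tte()]
#' @export
critical_power <- function(power, duration,
                           method = c("inverse_time", "work_time")) {
  method <- match.arg(method)
  power <- as.double(power)
  duration <- as.double(duration)
  if (length(power) != length(duration)) {
    stop_critpow("power and duration must have the same length")
  }
  if (length(power) < 2L) stop_critpow("at least 2 (power, duration) points are required")
  if (anyNA(power) || anyNA(duration) || any(!is.finite(c(power, duration)))) {
    stop_critpow("non-finite inputs")
  }
  if (any(duration <= 0)) stop_critpow("durations must be positive")
  if (anyDuplicated(duration)) {
    stop_critpow("duplicate durations make the design singular")
  }
  if (method == "inverse_time") {
    fit <- stats::lm(power ~ I(1 / duration))
    cf <- stats::coef(fit)
    cp <- unname(cf[1L]); wp <- unname(cf[2L])
    se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
    se_cp <- unname(se[1L]); se_wp <- unname(se[2L])
  } else {
    work <- power * duration
    fit <- stats::lm(work ~ duration)
    cf <- stats::coef(fit)
    wp <- unname(cf[1L]); cp <- unname(cf[2L])
    se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
    se_wp <- unname(se[1L]); se_cp <- unname(se[2L])
  }
  r2 <- suppressWarnings(summary(fit)$r.squared)  # silence perfect-fit note
  if (length(power) == 2L) r2 <- 1  # exact interpolation
  if (cp <= 0 || wp <= 0) {
    warning("critical_power: fit returned non-positive CP or W'; inspect the data",
            call. = FALSE)
  }
  structure(list(cp = cp, w_prime = wp, r_squared = r2,
                 se_cp = se_cp, se_w_prime = se_wp,
                 n_points = length(power), method = method, lm = fit,
                 data = data.frame(power = power, duration = duration)),
            class = "cpfit")
}

#' @export
print.cpfit <- function(x, digits = 4, ...) {
  cat(sprintf("Critical power model (%s), %d points\n", x$method, x$n_points))
  cat(sprintf("  CP = %s W (SE %s)\n", format(x$cp, digits = digits),
              format(x$se_cp, digits = 3)))
  cat(sprintf("  W' = %s J (SE %s)\n", format(x$w_prime, digits = digits),
              format(x$se_w_prime, digits = 3)))
  cat(sprintf("  R-squared = %s\n", format(x$r_squared, digits = digits)))
  invisible(x)
}

#' @export
summary.cpfit <- function(object, ...) {
  structure(list(fit = object, lm_summary = summary(object$lm)),
            class = "summary.cpfit")
}

#' @export
print.summary.cpfit <- function(x, ...) {
  print(x$fit)
  cat("\nUnderlying regression:\n")
  stats::printCoefmat(x$lm_summary$coefficients)
  invisible(x)
}

#' @export
coef.cpfit <- function(object, ...) {
  c(cp = object$cp, w_prime = object$w_prime)
}

#' @export
residuals.cpfit <- function(object, ...) {
  object$data$power - predict(object, object$data$duration)
}

#' Predict sustainable power for a duration
#'
#' @param object A [critical_power()] fit.
#' @param duration Durations (s), positive.
#' @param ... Unused.
#' @return Predicted power `CP + W'/duration` (W).
#' @export
predict.cpfit <- function(object, duration, ...) {
  if (any(duration <= 0)) stop_critpow("durations must be positive")
  object$cp + object$w_prime / duration
}

#' @export
plot.cpfit <- function(x, ...) {
  d <- x$data
  tt <- seq(min(d$duration) * 0.8, max(d$duration) * 1.2, length.out = 200)
  graphics::plot(d$duration, d$power, xlab = "Time to exhaustion (s)",
                 ylab = "Power (W)", pch = 19,
                 ylim = range(c(d$power, x$cp)), ...)
  graphics::lines(tt, predict(x, tt))
  graphics::abline(h = x$cp, lty = 2)
  graphics::legend("topright", bty = "n",
                   legend = c(sprintf("CP = %.0f W", x$cp),
                              sprintf("W' = %.0f J", x$w_prime)))
  invisible(x)
}

#' Prescribe a constant power for a target time to exhaustion
#'
#' Inverts the fitted hyperbola: the power predicted to exhaust the athlete
#' in `target_tte_s` seconds is `CP + W'/target_tte_s`.  Targets outside
#' 60-600 s (the 1-10 min range the protocol aims for) trigger a warning.
#'
#' @param fit A [critical_power()] fit.
#' @param target_tte_s Target time to exhaustion (s), > 0.
#' @return Prescribed power (W).
#' @export
prescribe_power <- function(fit, target_tte_s) {
  stopifnot(inherits(fit, "cpfit"))
  if (!is_scalar_number(target_tte_s) || target_tte_s <= 0) {
    stop_critpow("target_tte_s must be > 0")
  }
  if (target_tte_s < 60 || target_tte_s > 600) {
    warning("target time to exhaustion outside the 1-10 min protocol range",
            call. = FALSE)
  }
  fit$cp + fit$w_prime / target_tte_s
}

#' Predict time to exhaustion at a constant power
#'
#' Under the two-parameter model, exhaustion occurs when W' is fully
#' depleted: `t = W'/(P - CP)`.  Powers at or below CP are sustainable
#' indefinitely and raise an error.
#'
#' @param fit A [critical_power()] fit.
#' @param power Constant power (W), > CP.
#' @return Predicted time to exhaustion (s).
#' @export
predicted_tte <- function(fit, power) {
  stopifnot(inherits(fit, "cpfit"))
  if (!is_scalar_number(power)) stop_critpow("power must be a number")
  if (power <= fit$cp) {
    stop_critpow("power <= CP: predicted duration is infinite")
  }
  fit$w_prime / (power - fit$cp)
}
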