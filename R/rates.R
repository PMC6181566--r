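#' Convert a rate to the canonical per-minute unit
#'
#' All kinetic rates in the package are stored per minute. This helper
#' normalizes rates given per second, per minute, or per hour.
#'
#' @param value numeric rate(s) in the given unit.
#' @param unit one of `"min"`, `"s"`, `"h"` (aliases `"sec"`, `"second"`,
#'   `"minute"`, `"hour"` accepted).
#' @return numeric rate(s) per minute.
#' @export
#' @examples
#' per_minute(1 / 43, "s")   # unbinding rate (43 s)^-1 in min^-1
per_minute <- function(value, unit = "min") {
  unit <- match.arg(tolower(unit),
                    c("min", "minute", "minutes", "s", "sec", "second",
                      "seconds", "h", "hr", "hour", "hours"))
  fac <- switch(substr(unit, 1, 1), m = 1, s = 60, h = 1 / 60)
  value * fac
}

#' Kinetic rate constants of the receptor-slot model
#'
#' Bundles the four first-order rates of the model: `alpha`, the binding rate
#' of a pooled receptor to an empty slot (per receptor per empty slot);
#' `beta`, the unbinding rate of a slot-bound receptor; `gamma`, the receptor
#' externalization rate (receptors added to the pool per unit time); and
#' `delta`, the internalization rate of a pooled receptor. The canonical time
#' unit is minutes; use `unit` to supply values in another unit.
#'
#' @param alpha binding rate to slots, per (receptor x empty slot).
#' @param beta unbinding rate from slots, per bound receptor.
#' @param gamma externalization rate, receptors per unit time.
#' @param delta internalization rate, per pooled receptor.
#' @param unit time unit of the supplied values (see [per_minute()]).
#' @return an object of class `"rate_constants"`: a named list with elements
#'   `alpha`, `beta`, `gamma`, `delta`, all per minute.
#' @export
#' @examples
#' rate_constants(alpha = 0.0093, beta = 60 / 43, gamma = 25.1, delta = 1 / 14)
rate_constants <- function(alpha, beta, gamma, delta, unit = "min") {
  r <- vapply(list(alpha = alpha, beta = beta, gamma = gamma, delta = delta),
              function(x) per_minute(as.numeric(x), unit), numeric(1))
  if (any(!is.finite(r)) || any(r < 0))
    stop("all rate constants must be finite and >= 0")
  structure(as.list(r), class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("Rate constants (per minute):\n")
  cat(sprintf("  alpha = %.6g  (slot binding, per receptor x empty slot)\n", x$alpha))
  cat(sprintf("  beta  = %.6g  (slot unbinding)\n", x$beta))
  cat(sprintf("  gamma = %.6g  (externalization, receptors/min)\n", x$gamma))
  cat(sprintf("  delta = %.6g  (internalization)\n", x$delta))
  cat(sprintf("  derived: rho = beta/alpha = %.6g", x$beta / x$alpha))
  if (x$alpha * x$gamma > 0)
    cat(sprintf(", F = %.4g", filling_fraction(x)))
  cat("\n")
  invisible(x)
}

#' Convert an exponential half-life to a rate constant
#'
#' A first-order process with half-life `h` has rate `ln(2)/h` and mean
#' lifetime `h/ln(2)`; e.g. a 10-minute surface half-life of a receptor
#' corresponds to an internalization rate with mean lifetime of about 14 min.
#'
#' @param halflife half-life, in the given unit.
#' @param unit time unit of `halflife` (the returned rate is per minute).
#' @return rate per minute.
#' @export
#' @examples
#' 1 / halflife_to_rate(10)       # mean surface lifetime ~ 14.4 min
#' 1 / halflife_to_rate(30, "s")  # mean slot dwell time ~ 43 s (0.72 min)
halflife_to_rate <- function(halflife, unit = "min") {
  if (!is.numeric(halflife) || length(halflife) != 1L || !is.finite(halflife) ||
      halflife <= 0)
    stop("'halflife' must be a single positive number")
  h_min <- halflife / per_minute(1, unit)  # convert duration to minutes
  log(2) / h_min
}

#' Dimensionless removal ratio (beta*delta)/(alpha*gamma)
#'
#' The ratio of the rates removing receptors from slots (unbinding, then
#' internalization) to those delivering them (externalization, then binding).
#' It is the single control parameter of the long-term filling fraction.
#'
#' @param rates a [rate_constants()] object.
#' @return dimensionless removal ratio.
#' @export
removal_ratio <- function(rates) {
  (rates$beta * rates$delta) / (rates$alpha * rates$gamma)
}

#' Long-term filling fraction F
#'
#' At the global fixed point every synapse has the same fraction of occupied
#' slots, `F = 1 / (1 + beta*delta/(alpha*gamma))`, independent of slot
#' counts.
#'
#' @param rates a [rate_constants()] object.
#' @return filling fraction in (0, 1].
#' @export
#' @examples
#' r <- calibrate_rates(F = 0.7, phi = 2.67, S = 188)
#' filling_fraction(r)  # 0.7
filling_fraction <- function(rates) {
  ag <- rates$alpha * rates$gamma
  bd <- rates$beta * rates$delta
  if (ag == 0) {
    if (bd == 0) stop("filling fraction undefined: alpha*gamma = beta*delta = 0")
    return(0)
  }
  1 / (1 + bd / ag)
}

#' Calibrate the slot-binding rate alpha from experimental targets
#'
#' Solves for the binding rate that yields a desired long-term filling
#' fraction `F` given the relative pool size `phi`, the total slot count `S`
#' and the unbinding rate `beta`: `alpha = beta / (phi * S * (1 - F))`.
#' `S * (1 - F)` is the number of empty slots at steady state, so binding
#' must be fast when few slots are empty and the pool is relatively small.
#'
#' @param F target long-term filling fraction, in (0, 1).
#' @param phi target relative pool size `p_inf / W_inf` (> 0).
#' @param S total number of slots (> 0).
#' @param beta unbinding rate per minute; default (43 s)^-1.
#' @return alpha, per minute.
#' @export
#' @examples
#' calibrate_alpha(F = 0.5, phi = 2.67, S = 188)  # ~0.0056 min^-1
calibrate_alpha <- function(F, phi, S, beta = 60 / 43) {
  if (!is.finite(F) || F <= 0 || F >= 1)
    stop("'F' must lie strictly between 0 and 1")
  if (!is.finite(phi) || phi <= 0) stop("'phi' must be > 0")
  if (!is.finite(S) || S <= 0) stop("'S' must be > 0")
  beta / (phi * S * (1 - F))
}

#' Calibrate the externalization rate gamma from experimental targets
#'
#' The steady-state pool is `p_inf = gamma / delta` and the target pool is
#' `phi * W_inf = phi * F * S`, so `gamma = delta * phi * F * S`.
#'
#' @param F target long-term filling fraction.
#' @param phi target relative pool size.
#' @param S total number of slots.
#' @param delta internalization rate per minute; default (14 min)^-1.
#' @return gamma, receptors per minute.
#' @export
#' @examples
#' calibrate_gamma(F = 0.7, phi = 2.67, S = 188)  # ~25.1 min^-1
calibrate_gamma <- function(F, phi, S, delta = 1 / 14) {
  if (any(c(F, phi, S, delta) < 0)) stop("all arguments must be >= 0")
  delta * phi * F * S
}

#' Calibrate a full rate set from (F, phi, S)
#'
#' Convenience wrapper combining [calibrate_alpha()] and [calibrate_gamma()]
#' with the default unbinding and internalization rates: `beta = (43 s)^-1`
#' (slot dwell half-life 30 s) and `delta = (14 min)^-1` (surface half-life
#' 10 min). The round trip `filling_fraction(calibrate_rates(F, ...)) == F`
#' holds to machine precision.
#'
#' @inheritParams calibrate_alpha
#' @param delta internalization rate per minute.
#' @return a [rate_constants()] object.
#' @export
calibrate_rates <- function(F, phi, S, beta = 60 / 43, delta = 1 / 14) {
  rate_constants(alpha = calibrate_alpha(F, phi, S, beta),
                 beta  = beta,
                 gamma = calibrate_gamma(F, phi, S, delta),
                 delta = delta)
}

#' Externalization rate achieving a target pool size with alpha held fixed
#'
#' When the binding rate is fixed (rather than calibrated), the
#' externalization rate required for a relative pool size `phi` is
#' `gamma = delta * (S * phi - beta / alpha)`. The implied long-term filling
#' fraction is then `F = 1 - beta / (alpha * phi * S)`.
#'
#' @param phi target relative pool size.
#' @param S total number of slots.
#' @param rates a [rate_constants()] object whose `alpha`, `beta`, `delta`
#'   are used (`gamma` is ignored).
#' @return gamma per minute, with the implied filling fraction attached as
#'   attribute `"implied_F"`.
#' @export
#' @examples
#' r <- rate_constants(alpha = 0.0093, beta = 60 / 43, gamma = 1, delta = 1 / 14)
#' gamma_for_pool_with_fixed_alpha(phi = 5, S = 188, rates = r)  # ~56.4
gamma_for_pool_with_fixed_alpha <- function(phi, S, rates) {
  if (!is.finite(phi) || phi < 0 || !is.finite(S) || S < 0)
    stop("'phi' and 'S' must be finite and >= 0")
  rho <- rates$beta / rates$alpha
  if (S * phi <= rho)
    stop("pool target unreachable with fixed alpha: need S*phi > beta/alpha")
  g <- rates$delta * (S * phi - rho)
  structure(g, implied_F = 1 - rho / (phi * S))
}

#' Relative pool size phi = p / W
#'
#' @param p pool size (receptors not bound in any synapse).
#' @param W total number of slot-bound receptors.
#' @return the ratio `p / W`.
#' @export
relative_pool_size <- function(p, W) {
  if (!is.finite(W) || W <= 0) stop("'W' must be > 0")
  if (p < 0) stop("'p' must be >= 0")
  p / W
}
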