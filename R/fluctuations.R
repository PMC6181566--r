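#' Per-synapse coefficient of variation of bound receptor number
#'
#' The CV of synapse `i` is the standard deviation of its sampled bound
#' receptor count divided by its time average, in percent, computed over the
#' samples after a burn-in. Synapses with zero mean occupancy are returned as
#' `NA` (they carry no relative-fluctuation information and are excluded from
#' power-law fits).
#'
#' @param run a `"stochastic_run"` from [gillespie_run()].
#' @param burn_in initial period to discard, minutes (default 2).
#' @return numeric vector of CVs in percent, one per synapse (`NA` where the
#'   mean is zero).
#' @export
cv_per_synapse <- function(run, burn_in = 2) {
  keep <- run$time >= burn_in
  if (!any(keep)) stop("run shorter than 'burn_in'")
  w <- run$w[keep, , drop = FALSE]
  m <- colMeans(w)
  # population sd over the sampling window (time-average statistics)
  v <- colMeans(w^2) - m^2
  s <- sqrt(pmax(v, 0))
  ifelse(m > 0, 100 * s / m, NA_real_)
}

#' Fit a power law CV = a * x^b in double-log space
#'
#' Ordinary least squares of `log10(y)` on `log10(x)`; the scale factor is
#' `a = 10^intercept` (the CV in percent at unit mean occupancy) and the
#' exponent `b` is the slope. For the receptor-slot model the exponent is
#' close to -1/2: fluctuations decline with one over the square root of the
#' mean number of bound receptors.
#'
#' @param x mean occupancies (`F * s_i`), all > 0.
#' @param y CVs in percent, all > 0 (`NA` pairs are dropped).
#' @return an object of class `"power_law_fit"`: list with `a`, `b`,
#'   `residual_sd` (of the log10 residuals), `n_points`.
#' @export
#' @examples
#' fit_power_law(c(1, 10, 100), 10 * c(1, 10, 100)^-0.5)  # a = 10, b = -0.5
fit_power_law <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) stop("need at least 2 points to fit a power law")
  if (any(x <= 0) || any(y <= 0)) stop("'x' and 'y' must be positive")
  fit <- stats::lm(log10(y) ~ log10(x))
  co <- stats::coef(fit)
  structure(list(a = 10^co[[1]], b = co[[2]],
                 residual_sd = stats::sd(stats::residuals(fit)),
                 n_points = length(x)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Power-law fit CV = a * (F s)^b: a = %.4g%%, b = %.4g (%d points)\n",
              x$a, x$b, x$n_points))
  invisible(x)
}

#' Fluctuation experiment: CV power laws across filling fractions or pool sizes
#'
#' Reproduces the steady-state fluctuation analysis: for each grid point,
#' rates are calibrated (mode `"filling"`: vary the target filling fraction
#' at fixed relative pool size; mode `"pool"`: hold alpha fixed and set gamma
#' to reach each relative pool size, which changes the implied filling
#' fraction), `n_runs` independent Gillespie runs are simulated from the
#' rounded fixed point, per-synapse CVs are averaged across runs, and a power
#' law `CV = a (F s)^b` is fitted through the per-synapse averages in
#' double-log space.
#'
#' @param values grid of filling fractions (mode `"filling"`) or relative
#'   pool sizes (mode `"pool"`).
#' @param mode `"filling"` or `"pool"`.
#' @param slots integer per-synapse slot counts (default the 7-synapse group
#'   1, 2, 5, 10, 20, 50, 100).
#' @param phi relative pool size used in mode `"filling"`.
#' @param alpha_fixed binding rate used in mode `"pool"`, per minute.
#' @param beta,delta unbinding and internalization rates, per minute.
#' @param n_runs independent runs per grid point.
#' @param duration simulated minutes per run.
#' @param burn_in discarded initial period, minutes.
#' @param seed base seed; run `j` of grid point `i` uses
#'   `seed + 1000 * i + j`.
#' @return data.frame with one row per grid point: `mode`, `F`, `phi`,
#'   `alpha`, `gamma`, `a`, `b`, plus the per-synapse mean CVs as attribute
#'   `"cv_matrix"`.
#' @export
#' @examples
#' \donttest{
#' cv_experiment(c(0.5, 0.9), n_runs = 3, duration = 10, seed = 1)
#' }
cv_experiment <- function(values, mode = c("filling", "pool"),
                          slots = c(1, 2, 5, 10, 20, 50, 100),
                          phi = 2.67, alpha_fixed = 0.0093,
                          beta = 60 / 43, delta = 1 / 14,
                          n_runs = 10, duration = 30, burn_in = 2,
                          seed = 1) {
  mode <- match.arg(mode)
  S <- sum(slots)
  rows <- vector("list", length(values))
  cvm <- matrix(NA_real_, length(values), length(slots))
  for (i in seq_along(values)) {
    v <- values[i]
    if (mode == "filling") {
      rates <- calibrate_rates(v, phi, S, beta = beta, delta = delta)
      F_i <- v; phi_i <- phi
    } else {
      base <- rate_constants(alpha_fixed, beta, 1, delta)
      g <- gamma_for_pool_with_fixed_alpha(v, S, base)
      rates <- rate_constants(alpha_fixed, beta, as.numeric(g), delta)
      F_i <- attr(g, "implied_F"); phi_i <- v
    }
    st <- stochastic_init(rates, slots)
    cvs <- vapply(seq_len(n_runs), function(j) {
      run <- gillespie_run(st, rates, t_end = duration,
                           seed = seed + 1000L * i + j)
      cv_per_synapse(run, burn_in = burn_in)
    }, numeric(length(slots)))
    cv_mean <- rowMeans(cvs, na.rm = TRUE)
    cvm[i, ] <- cv_mean
    fit <- fit_power_law(F_i * slots, cv_mean)
    rows[[i]] <- data.frame(mode = mode, F = F_i, phi = phi_i,
                            alpha = rates$alpha, gamma = rates$gamma,
                            a = fit$a, b = fit$b)
  }
  out <- do.call(rbind, rows)
  attr(out, "cv_matrix") <- cvm
  out
}
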