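#' Drift of the total receptor number under separation of timescales
#'
#' On the slow timescale the fast binding/unbinding equilibrates at every
#' instant, so the pool is `p*(R) = R - W*(R)` and the total receptor number
#' obeys the one-dimensional equation
#' `dR/dt = gamma + delta * F*(R) * S - delta * R`,
#' with `F*(R)` the fast-timescale filling fraction at `rho = beta/alpha`.
#' Near `R = 0` the drift is just the externalization rate `gamma`; near the
#' fixed point it is linear with slope about `-delta`, so `R` approaches
#' `gamma/delta + F*S` exponentially with time constant `1/delta`.
#'
#' @param R total receptor number (scalar or vector).
#' @param rates a [rate_constants()] object.
#' @param S total slot count.
#' @return dR/dt, receptors per minute.
#' @export
reduced_rdot <- function(R, rates, S) {
  if (any(R < 0) || S < 0) stop("'R' and 'S' must be >= 0")
  rho <- rates$beta / rates$alpha
  W <- fast_w_star(R, S, rho)
  rates$gamma + rates$delta * W - rates$delta * R
}

#' Integrate the reduced receptor-accumulation dynamics
#'
#' Forward-Euler integration of [reduced_rdot()]. From any non-negative
#' starting receptor number the trajectory converges monotonically to
#' `R_inf = gamma/delta + F*S = (1 + phi) * F * S` for calibrated rates.
#'
#' @param R0 initial total receptor number (>= 0).
#' @param rates a [rate_constants()] object.
#' @param S total slot count.
#' @param t_end end time in minutes.
#' @param dt Euler step in minutes.
#' @param sample_every sampling interval in minutes.
#' @return data.frame with columns `time_min` and `R`.
#' @export
#' @examples
#' r <- calibrate_rates(F = 0.9, phi = 2.67, S = 10000)
#' tr <- integrate_reduced(0, r, S = 10000, t_end = 120)
#' tail(tr$R, 1)  # ~33030
integrate_reduced <- function(R0, rates, S, t_end, dt = 0.01,
                              sample_every = 0.1) {
  if (!is.finite(dt) || dt <= 0) stop("'dt' must be > 0")
  if (R0 < 0) stop("'R0' must be >= 0")
  n_steps <- max(0L, as.integer(round(t_end / dt)))
  stride <- max(1L, as.integer(round(sample_every / dt)))
  R <- R0
  out_t <- numeric(n_steps %/% stride + 1L)
  out_R <- numeric(length(out_t))
  k <- 0L
  for (step in 0:n_steps) {
    if (step %% stride == 0L) {
      k <- k + 1L
      out_t[k] <- step * dt
      out_R[k] <- R
    }
    if (step == n_steps) break
    R <- max(R + dt * reduced_rdot(R, rates, S), 0)
  }
  data.frame(time_min = out_t[1:k], R = out_R[1:k])
}
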