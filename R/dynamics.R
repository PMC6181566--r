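#' System state of the receptor-slot model
#'
#' Snapshot of the model: per-synapse slot counts `s_i`, bound receptor
#' numbers `w_i` (the synaptic efficacies, `0 <= w_i <= s_i`), the shared
#' pool `p >= 0`, and the time in minutes.
#'
#' @param slots per-synapse slot counts (>= 0).
#' @param w per-synapse bound receptors; defaults to all zero.
#' @param p pool size (>= 0).
#' @param t time in minutes.
#' @return an object of class `"system_state"`.
#' @export
#' @examples
#' system_state(slots = c(40, 60, 80), w = 0.9 * c(40, 60, 80), p = 432.5)
system_state <- function(slots, w = rep(0, length(slots)), p = 0, t = 0) {
  slots <- as.numeric(slots); w <- as.numeric(w)
  if (length(w) != length(slots))
    stop("'w' and 'slots' must have the same length")
  if (any(slots < 0)) stop("slot counts must be >= 0")
  if (any(w < -1e-12) || any(w - slots > 1e-9 * pmax(1, slots)))
    stop("bound receptors must satisfy 0 <= w_i <= s_i")
  if (p < 0) stop("pool size must be >= 0")
  structure(list(t = as.numeric(t), s = slots, w = pmin(pmax(w, 0), slots),
                 p = as.numeric(p)),
            class = "system_state")
}

#' State at the long-term fixed point
#'
#' Builds a [system_state()] positioned exactly at the steady state of the
#' given rates: `w_i = F * s_i`, `p = gamma/delta`.
#'
#' @param rates a [rate_constants()] object.
#' @param slots per-synapse slot counts.
#' @return a `"system_state"`.
#' @export
steady_state_init <- function(rates, slots) {
  ss <- long_term_steady_state(rates, slots)
  system_state(slots = slots, w = ss$w_inf, p = ss$p_inf)
}

#' @export
print.system_state <- function(x, ...) {
  cat(sprintf("System state at t = %g min: N = %d synapses\n", x$t, length(x$s)))
  cat("  s =", paste(signif(x$s, 5), collapse = " "), "\n")
  cat("  w =", paste(signif(x$w, 5), collapse = " "), "\n")
  cat(sprintf("  p = %.6g, W = %.6g, R = %.6g\n", x$p, sum(x$w), sum(x$w) + x$p))
  invisible(x)
}

#' A scheduled perturbation of the pool or the slot counts
#'
#' Events are applied atomically at the integration step containing their
#' scheduled time. Pool events rescale or set the pool size; slot events
#' rescale or set the slot counts of the targeted synapses. If a slot event
#' shrinks a synapse below its current occupancy, the excess bound receptors
#' are returned to the pool so that the total receptor number is conserved.
#'
#' @param time event time in minutes (>= 0).
#' @param kind one of `"scale_pool"`, `"set_pool"`, `"scale_slots"`,
#'   `"set_slots"`.
#' @param value the scale factor (for `scale_*`) or the new value (for
#'   `set_*`).
#' @param targets synapse indices affected by slot events; ignored for pool
#'   events.
#' @return an object of class `"sim_event"`.
#' @export
#' @examples
#' sim_event(2, "scale_pool", 2)                     # double the pool at 2 min
#' sim_event(2, "scale_slots", 2, targets = c(1, 3)) # double slots of synapses 1,3
sim_event <- function(time, kind, value, targets = NULL) {
  kind <- match.arg(kind, c("scale_pool", "set_pool", "scale_slots", "set_slots"))
  if (!is.finite(time) || time < 0) stop("event time must be >= 0")
  if (!is.finite(value) || value < 0) stop("event value must be >= 0")
  if (kind %in% c("scale_slots", "set_slots") && is.null(targets))
    stop("slot events require 'targets'")
  structure(list(time = time, kind = kind, value = value,
                 targets = targets), class = "sim_event")
}

# Apply one event to (s, w, p); returns the modified triple.
apply_event <- function(ev, s, w, p) {
  switch(ev$kind,
    scale_pool = { p <- p * ev$value },
    set_pool   = { p <- ev$value },
    scale_slots = ,
    set_slots  = {
      idx <- ev$targets
      if (any(idx < 1 | idx > length(s))) stop("event targets out of range")
      s[idx] <- if (ev$kind == "scale_slots") s[idx] * ev$value else ev$value
      over <- pmax(w[idx] - s[idx], 0)   # shrunk below occupancy: free receptors
      w[idx] <- w[idx] - over
      p <- p + sum(over)
    })
  list(s = s, w = w, p = p)
}

#' Time derivatives of the mass-action model
#'
#' The core kinetic equations: each synapse gains receptors from the pool in
#' proportion to its empty slots and loses them by unbinding,
#' `dw_i/dt = -beta w_i + alpha_i p (s_i - w_i)`; the pool balances
#' externalization, internalization, and the net flux to the synapses,
#' `dp/dt = -delta p + gamma + sum(beta w_i) - sum(alpha_i p (s_i - w_i))`.
#' With `gamma = delta = 0` the total receptor number is conserved exactly.
#'
#' @param state a [system_state()].
#' @param rates a [rate_constants()] object.
#' @param alpha_i optional per-synapse binding rates overriding `rates$alpha`
#'   (used for synapse-specific potentiation).
#' @return list with `dw` (per synapse) and `dp`, per minute.
#' @export
model_derivatives <- function(state, rates, alpha_i = NULL) {
  a <- if (is.null(alpha_i)) rates$alpha else alpha_i
  if (length(a) != 1L && length(a) != length(state$w))
    stop("'alpha_i' must have length 1 or N")
  bind <- a * state$p * (state$s - state$w)
  unbind <- rates$beta * state$w
  list(dw = bind - unbind,
       dp = -rates$delta * state$p + rates$gamma + sum(unbind) - sum(bind))
}

#' Integrate the model with forward Euler
#'
#' Fixed-step Euler integration of the mass-action equations, with optional
#' scheduled events (pool and slot perturbations) and optional waveforms that
#' modulate per-synapse binding rates and slot counts continuously in time
#' (the potentiation model). Events are applied atomically at the first step
#' whose time reaches their schedule. A step that would push some `w_i` past
#' `s_i` (or below 0) by more than a small tolerance aborts with an error
#' advising a smaller `dt`; sub-tolerance overshoot is clipped with the
#' excess returned to the pool, so receptors are conserved.
#'
#' @param state0 initial [system_state()].
#' @param rates a [rate_constants()] object.
#' @param t_end end time in minutes.
#' @param dt Euler step in minutes (default 0.005 min = 0.3 s, about an order
#'   of magnitude below the fastest relaxation time under default
#'   parameters).
#' @param events list of [sim_event()] objects (any order).
#' @param waveforms optional list with functions `alpha_factor(t)` and/or
#'   `slot_factor(t)`, each returning a length-`N` vector of multiplicative
#'   factors applied to the baseline binding rate and the baseline slot
#'   counts at absolute time `t` (minutes).
#' @param sample_every sampling interval in minutes (rounded to a multiple of
#'   `dt`).
#' @return an object of class `"trajectory"`: list with `time` (minutes),
#'   matrices `w` and `s` (samples x synapses), vectors `p`, `W`, `R`, and
#'   the integration settings as attributes.
#' @export
#' @examples
#' r <- calibrate_rates(F = 0.9, phi = 2.67, S = 180)
#' st <- steady_state_init(r, slots = c(40, 60, 80))
#' tr <- integrate_model(st, r, t_end = 10,
#'                       events = list(sim_event(2, "scale_pool", 2)))
integrate_model <- function(state0, rates, t_end, dt = 0.005,
                            events = list(), waveforms = NULL,
                            sample_every = 0.05) {
  if (!is.finite(dt) || dt <= 0) stop("'dt' must be > 0")
  if (t_end < state0$t) stop("'t_end' must be >= start time")
  N <- length(state0$s)
  n_steps <- max(0L, as.integer(round((t_end - state0$t) / dt)))
  stride <- max(1L, as.integer(round(sample_every / dt)))
  ev <- events[order(vapply(events, `[[`, numeric(1), "time"))]
  ev_times <- vapply(ev, `[[`, numeric(1), "time")
  next_ev <- 1L

  s0 <- state0$s; s <- s0; w <- state0$w; p <- state0$p; t <- state0$t
  af <- waveforms$alpha_factor; sf <- waveforms$slot_factor
  n_samp <- n_steps %/% stride + 1L
  out_t <- numeric(n_samp)
  out_w <- matrix(NA_real_, n_samp, N)
  out_s <- matrix(NA_real_, n_samp, N)
  out_p <- numeric(n_samp)
  k <- 0L
  tol <- 1e-6

  for (step in 0:n_steps) {
    # pending events fire before the state is sampled or advanced
    while (next_ev <= length(ev) && ev_times[next_ev] <= t + 1e-12) {
      upd <- apply_event(ev[[next_ev]], s, w, p)
      s <- upd$s; s0 <- s / if (is.null(sf)) 1 else sf(t)
      w <- upd$w; p <- upd$p
      next_ev <- next_ev + 1L
    }
    s_t <- if (is.null(sf)) s else s0 * sf(t)
    if (step %% stride == 0L) {
      k <- k + 1L
      out_t[k] <- t; out_w[k, ] <- w; out_s[k, ] <- s_t; out_p[k] <- p
    }
    if (step == n_steps) break
    a_t <- if (is.null(af)) rates$alpha else rates$alpha * af(t)
    bind <- a_t * p * (s_t - w)
    unbind <- rates$beta * w
    w_new <- w + dt * (bind - unbind)
    p_new <- p + dt * (-rates$delta * p + rates$gamma + sum(unbind) - sum(bind))
    # next step's slot counts bound the clip (waveform may move s)
    s_next <- if (is.null(sf)) s else s0 * sf(t + dt)
    over <- pmax(w_new - s_next, 0) + pmax(-w_new, 0)
    if (any(over > tol * pmax(1, s_next)) || p_new < -tol)
      stop("integration overshoot: decrease 'dt'")
    clip_hi <- pmin(w_new, s_next)
    w_clip <- pmax(clip_hi, 0)
    p_new <- p_new + sum(w_new - w_clip)   # return clipped excess to the pool
    w <- w_clip
    p <- max(p_new, 0)
    t <- state0$t + (step + 1) * dt
  }
  structure(list(time = out_t[1:k], w = out_w[1:k, , drop = FALSE],
                 s = out_s[1:k, , drop = FALSE], p = out_p[1:k],
                 W = rowSums(out_w[1:k, , drop = FALSE]),
                 R = rowSums(out_w[1:k, , drop = FALSE]) + out_p[1:k]),
            class = "trajectory",
            rates = rates, dt = dt, events = events)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d samples, t in [%g, %g] min, N = %d synapses\n",
              length(x$time), x$time[1], x$time[length(x$time)], ncol(x$w)))
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  d <- data.frame(time_min = x$time)
  wn <- as.data.frame(x$w)
  names(wn) <- paste0("w_", seq_len(ncol(x$w)))
  cbind(d, wn, p = x$p, W = x$W, R = x$R)
}

#' Final state of a trajectory
#'
#' @param traj a `"trajectory"` object.
#' @return a [system_state()] at the last sample.
#' @export
final_state <- function(traj) {
  n <- length(traj$time)
  system_state(slots = traj$s[n, ], w = traj$w[n, ], p = traj$p[n],
               t = traj$time[n])
}
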