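# Scripted experiments: pool steps, slot steps, waveform-driven LTP, and the
# lognormal slot-count demonstration. All protocols report relative efficacy
# changes (x(t) - x(0-)) / x(0-) with the baseline taken just before the
# first perturbation.

protocol_result <- function(traj, baseline, extra = list()) {
  rel_w <- sweep(traj$w, 2, baseline$w, "/") - 1
  rel_p <- traj$p / baseline$p - 1
  structure(c(list(trajectory = traj, rel_w = rel_w, rel_p = rel_p,
                   baseline = baseline), extra),
            class = "protocol_result")
}

#' @export
print.protocol_result <- function(x, ...) {
  cat(sprintf("Protocol result: %d samples, N = %d synapses\n",
              length(x$trajectory$time), ncol(x$rel_w)))
  for (nm in intersect(c("peak_homo", "peak_hetero", "analytic_hetero"), names(x)))
    cat(sprintf("  %s = %.4g\n", nm, x[[nm]]))
  invisible(x)
}

#' Sudden manipulation of the receptor pool
#'
#' Starts the system at its long-term fixed point and, at `t_step`, rescales
#' the pool by `factor` (2 doubles it, 0 empties it). Receptors redistribute
#' within seconds to the fast equilibrium — multiplicatively, so the relative
#' efficacy change is identical for every synapse — and then drift back to
#' the original fixed point on the slow `1/delta` timescale.
#'
#' @param config a [run_config()]; the classic setup uses three synapses with
#'   40, 60 and 80 slots at `F = 0.9`, `phi = 2.67`.
#' @param factor pool scale factor (>= 0).
#' @param t_step perturbation time, minutes.
#' @param t_end end time, minutes.
#' @param dt Euler step, minutes.
#' @param sample_every sampling interval, minutes.
#' @return a `"protocol_result"`: the trajectory, the relative-change series
#'   `rel_w` (samples x synapses) and `rel_p`, the baseline state, and
#'   `peak_rel` (the largest-magnitude common relative change).
#' @export
#' @examples
#' res <- pool_step_protocol(run_config(), factor = 2, t_end = 10)
#' res$peak_rel
pool_step_protocol <- function(config = run_config(), factor = 2,
                               t_step = 2, t_end = 60, dt = 0.005,
                               sample_every = 0.05) {
  rates <- resolve_rates(config)
  st <- steady_state_init(rates, config$slots)
  traj <- integrate_model(st, rates, t_end, dt = dt,
                          events = list(sim_event(t_step, "scale_pool", factor)),
                          sample_every = sample_every)
  res <- protocol_result(traj, st)
  i_pk <- which.max(abs(res$rel_w[, 1]))
  res$peak_rel <- res$rel_w[i_pk, 1]
  res
}

#' Instantaneous slot addition: homosynaptic LTP with heterosynaptic LTD
#'
#' At `t_step` the slot counts of the targeted synapses are rescaled by
#' `factor` while the others are untouched. The enlarged synapses recruit
#' receptors from the shared pool, transiently depressing the unstimulated
#' synapses; those recover toward their original efficacies on the `1/delta`
#' timescale while the stimulated synapses remain permanently strengthened.
#'
#' @param config a [run_config()]; the classic setup uses four synapses with
#'   20, 40, 60 and 80 slots at `F = 0.5`, `phi = 2.67`.
#' @param targets indices of the stimulated synapses.
#' @param factor slot scale factor.
#' @param t_step perturbation time, minutes.
#' @param t_end end time, minutes (long enough to see the recovery).
#' @param dt Euler step, minutes.
#' @param sample_every sampling interval, minutes.
#' @return a `"protocol_result"` with additional series `homo` and `hetero`
#'   (mean relative change over stimulated / unstimulated synapses),
#'   `peak_hetero` (most negative heterosynaptic change), and
#'   `analytic_hetero` (the fast-equilibrium prediction `(F* - F)/F`).
#' @export
#' @examples
#' res <- slot_step_protocol(run_config(target_F = 0.5,
#'                                      slots = c(20, 40, 60, 80)))
#' c(res$peak_hetero, res$analytic_hetero)
slot_step_protocol <- function(config = run_config(target_F = 0.5,
                                                   slots = c(20, 40, 60, 80)),
                               targets = c(1, 3), factor = 2,
                               t_step = 2, t_end = 120, dt = 0.005,
                               sample_every = 0.05) {
  rates <- resolve_rates(config)
  st <- steady_state_init(rates, config$slots)
  traj <- integrate_model(st, rates, t_end, dt = dt,
                          events = list(sim_event(t_step, "scale_slots", factor,
                                                  targets = targets)),
                          sample_every = sample_every)
  res <- protocol_result(traj, st)
  others <- setdiff(seq_along(config$slots), targets)
  res$homo <- rowMeans(res$rel_w[, targets, drop = FALSE])
  res$hetero <- rowMeans(res$rel_w[, others, drop = FALSE])
  res$peak_hetero <- min(res$hetero)
  S <- sum(config$slots)
  S_prime <- S + sum(config$slots[targets]) * (factor - 1)
  res$analytic_hetero <- heterosynaptic_change_curve(
    S_prime, F = filling_fraction(rates), phi = config$target_phi, S = S,
    rho = rates$beta / rates$alpha)
  res
}

#' Analytic heterosynaptic change after a slot-number jump
#'
#' Shortly after the total slot count jumps from `S` to `S_prime` (with the
#' total receptor number still at its pre-induction value
#' `R = (1 + phi) F S`), a synapse whose own slots did not change moves from
#' occupancy `F s_i` to `F* s_i`, so its relative change is `(F* - F)/F`.
#' Added slots (`S_prime > S`) give heterosynaptic depression; removed slots
#' give heterosynaptic potentiation. A large pool (`phi`) or high filling
#' fraction buffers the effect.
#'
#' @param S_prime total slot count after induction (vectorized).
#' @param F pre-induction filling fraction.
#' @param phi relative pool size.
#' @param S pre-induction total slot count.
#' @param rho beta/alpha; defaults to the calibrated value
#'   `phi * S * (1 - F)`.
#' @return relative heterosynaptic change(s) `(F* - F)/F`.
#' @export
#' @examples
#' heterosynaptic_change_curve(280, F = 0.5, phi = 2.67, S = 200)  # ~ -6.2%
heterosynaptic_change_curve <- function(S_prime, F, phi, S,
                                        rho = phi * S * (1 - F)) {
  if (any(S_prime <= 0)) stop("'S_prime' must be > 0")
  R <- (1 + phi) * F * S
  F_star <- vapply(S_prime, function(sp)
    fast_equilibrium(R, sp, rho)$F_star, numeric(1))
  (F_star - F) / F
}

#' Waveform specification for the LTP induction model
#'
#' During induction the stimulated synapses get (i) a transient rise of the
#' binding rate: linear ramp to `alpha_peak` times baseline over
#' `alpha_rise` minutes, then linear return over `alpha_fall` minutes —
#' the time course of CaMKII activation; and (ii) a slot-count change driven
#' by spine volume: a sigmoidal (logistic, pinned at both ends) rise to
#' `vol_peak` times baseline over `vol_rise` minutes, then exponential decay
#' to a sustained `vol_sustained` times baseline with time constant
#' `vol_tau`. Slot counts scale with volume to the power `slot_exponent`
#' (2/3: membrane surface area rather than volume), so the peak slot factor
#' is `vol_peak^(2/3)` (about 2.92) and the sustained factor
#' `vol_sustained^(2/3)` (about 1.59).
#'
#' @param stimulated indices of the potentiated synapses.
#' @param onset induction onset, minutes.
#' @param alpha_peak,alpha_rise,alpha_fall binding-rate waveform parameters
#'   (peak factor; rise and fall durations, minutes).
#' @param vol_peak,vol_rise,vol_sustained,vol_tau volume waveform parameters
#'   (peak and sustained factors; rise duration and decay constant, minutes).
#' @param slot_exponent exponent linking slot count to spine volume.
#' @return an object of class `"ltp_spec"`.
#' @export
ltp_spec <- function(stimulated = c(2, 3), onset = 2,
                     alpha_peak = 4, alpha_rise = 17 / 60, alpha_fall = 2,
                     vol_peak = 5, vol_rise = 2, vol_sustained = 2,
                     vol_tau = 5, slot_exponent = 2 / 3) {
  stopifnot(alpha_peak >= 1, vol_peak >= vol_sustained, vol_sustained >= 1,
            alpha_rise > 0, alpha_fall > 0, vol_rise > 0, vol_tau > 0)
  structure(list(stimulated = stimulated, onset = onset,
                 alpha_peak = alpha_peak, alpha_rise = alpha_rise,
                 alpha_fall = alpha_fall, vol_peak = vol_peak,
                 vol_rise = vol_rise, vol_sustained = vol_sustained,
                 vol_tau = vol_tau, slot_exponent = slot_exponent),
            class = "ltp_spec")
}

#' Binding-rate factor of the LTP waveform at time t
#'
#' @param t absolute time(s), minutes.
#' @param spec an [ltp_spec()].
#' @return multiplicative factor(s) (1 at baseline).
#' @export
ltp_alpha_factor <- function(t, spec = ltp_spec()) {
  u <- t - spec$onset
  up <- spec$alpha_rise
  dn <- spec$alpha_fall
  pk <- spec$alpha_peak
  f <- rep(1, length(u))
  ris <- u >= 0 & u < up
  fal <- u >= up & u < up + dn
  f[ris] <- 1 + (pk - 1) * u[ris] / up
  f[fal] <- pk - (pk - 1) * (u[fal] - up) / dn
  f
}

# Logistic pinned so the rise is exactly 1 at u=0 and vol_peak at u=vol_rise
# (steepness ~1% of amplitude at the unpinned endpoints), then exponential
# decay toward the sustained level; continuous at the join.
ltp_volume_factor <- function(t, spec = ltp_spec()) {
  u <- t - spec$onset
  k <- 2 * log(99) / spec$vol_rise          # 1%/99% crossing over the rise
  sig <- function(x) 1 / (1 + exp(-k * (x - spec$vol_rise / 2)))
  s0 <- sig(0); s1 <- sig(spec$vol_rise)
  f <- rep(1, length(u))
  ris <- u >= 0 & u < spec$vol_rise
  dec <- u >= spec$vol_rise
  f[ris] <- 1 + (spec$vol_peak - 1) * (sig(u[ris]) - s0) / (s1 - s0)
  f[dec] <- spec$vol_sustained + (spec$vol_peak - spec$vol_sustained) *
    exp(-(u[dec] - spec$vol_rise) / spec$vol_tau)
  f
}

#' Slot-count factor of the LTP waveform at time t
#'
#' The volume waveform raised to the `slot_exponent`.
#'
#' @inheritParams ltp_alpha_factor
#' @return multiplicative factor(s) (1 at baseline).
#' @export
ltp_slot_factor <- function(t, spec = ltp_spec()) {
  ltp_volume_factor(t, spec)^spec$slot_exponent
}

#' Waveform-driven LTP induction protocol
#'
#' Integrates the model with synapse-specific, time-varying binding rates and
#' slot counts given by the [ltp_spec()] waveforms applied to the stimulated
#' synapses. Reports the peak relative homosynaptic change (largest increase
#' among stimulated synapses) and the peak heterosynaptic change (largest
#' depression among unstimulated synapses).
#'
#' @param config a [run_config()]; defaults to four synapses with 20, 40, 60
#'   and 80 slots at `F = 0.9`, `phi = 2.67`.
#' @param spec an [ltp_spec()].
#' @param t_end end time, minutes.
#' @param dt Euler step, minutes.
#' @param sample_every sampling interval, minutes.
#' @return a `"protocol_result"` with `homo` and `hetero` series and scalars
#'   `peak_homo`, `peak_hetero`.
#' @export
#' @examples
#' res <- ltp_protocol(t_end = 10)
#' c(res$peak_homo, res$peak_hetero)
ltp_protocol <- function(config = run_config(target_F = 0.9,
                                             slots = c(20, 40, 60, 80)),
                         spec = ltp_spec(), t_end = 15, dt = 0.002,
                         sample_every = 0.02) {
  rates <- resolve_rates(config)
  N <- length(config$slots)
  if (any(spec$stimulated < 1 | spec$stimulated > N))
    stop("'spec$stimulated' out of range")
  mask <- as.numeric(seq_len(N) %in% spec$stimulated)
  waveforms <- list(
    alpha_factor = function(t) 1 + (ltp_alpha_factor(t, spec) - 1) * mask,
    slot_factor  = function(t) 1 + (ltp_slot_factor(t, spec) - 1) * mask)
  st <- steady_state_init(rates, config$slots)
  traj <- integrate_model(st, rates, t_end, dt = dt, waveforms = waveforms,
                          sample_every = sample_every)
  res <- protocol_result(traj, st)
  others <- setdiff(seq_len(N), spec$stimulated)
  res$homo <- rowMeans(res$rel_w[, spec$stimulated, drop = FALSE])
  res$hetero <- rowMeans(res$rel_w[, others, drop = FALSE])
  res$peak_homo <- max(res$homo)
  res$peak_hetero <- min(res$hetero)
  res
}

#' Peak LTP / heterosynaptic LTD as a function of pool size
#'
#' Runs [ltp_protocol()] over a grid of relative pool sizes and filling
#' fractions and tabulates the peak homosynaptic and heterosynaptic relative
#' changes. A small pool strongly reduces peak homosynaptic LTP and
#' amplifies heterosynaptic LTD; both effects are attenuated at high filling
#' fraction.
#'
#' @param phi_grid relative pool sizes to sweep.
#' @param F_set filling fractions to sweep.
#' @param slots per-synapse slot counts.
#' @param spec an [ltp_spec()].
#' @param t_end,dt integration settings per grid point, minutes.
#' @return data.frame with columns `F`, `phi`, `peak_homo`, `peak_hetero`.
#' @export
ltp_peak_sweep <- function(phi_grid = c(0.5, 1, 1.5, 2, 2.67, 3.5, 5),
                           F_set = c(0.5, 0.7, 0.9),
                           slots = c(20, 40, 60, 80),
                           spec = ltp_spec(), t_end = 15, dt = 0.002) {
  grid <- expand.grid(F = F_set, phi = phi_grid)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- run_config(target_F = grid$F[i], target_phi = grid$phi[i],
                      slots = slots)
    res <- ltp_protocol(cfg, spec = spec, t_end = t_end, dt = dt)
    data.frame(F = grid$F[i], phi = grid$phi[i],
               peak_homo = res$peak_homo, peak_hetero = res$peak_hetero)
  })
  do.call(rbind, out)
}

#' Lognormal per-synapse slot counts
#'
#' Draws slot counts from a lognormal distribution parameterized by the mean
#' and standard deviation of the variate itself (default mean 1.0, sd 0.2)
#' and rescales so the sample mean equals `target_mean_slots` exactly.
#' `sd = 0` returns equal counts.
#'
#' @param n_synapses number of synapses.
#' @param mean,sd mean and standard deviation of the lognormal variate.
#' @param target_mean_slots average slot count after scaling.
#' @param seed optional RNG seed.
#' @return numeric vector of `n_synapses` positive slot counts with mean
#'   `target_mean_slots`.
#' @export
#' @examples
#' s <- lognormal_slot_sampler(100, seed = 1)
#' mean(s)  # exactly 100
lognormal_slot_sampler <- function(n_synapses, mean = 1, sd = 0.2,
                                   target_mean_slots = 100, seed = NULL) {
  if (n_synapses < 1 || mean <= 0 || sd < 0 || target_mean_slots <= 0)
    stop("invalid sampler parameters")
  if (!is.null(seed)) set.seed(seed)
  if (sd == 0) return(rep(target_mean_slots, n_synapses))
  sigma2 <- log(1 + (sd / mean)^2)
  mu <- log(mean) - sigma2 / 2
  x <- stats::rlnorm(n_synapses, meanlog = mu, sdlog = sqrt(sigma2))
  x * target_mean_slots / base::mean(x)
}
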