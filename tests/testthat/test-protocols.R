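test_that("pool steps change every synapse by the same relative amount", {
  res <- pool_step_protocol(run_config(), factor = 2, t_end = 10)
  spread <- apply(res$rel_w, 1, function(x) diff(range(x)))
  expect_lt(max(spread), 1e-9)
  # the transient peak equals the fast-equilibrium prediction at R' = R + p
  r <- resolve_rates(run_config())
  st <- res$baseline
  fe <- fast_equilibrium(sum(st$w) + 2 * st$p, sum(st$s), r$beta / r$alpha)
  expect_equal(res$peak_rel, (fe$F_star - 0.9) / 0.9, tolerance = 0.02)
  # a lower filling fraction reacts more strongly to the same doubling
  res5 <- pool_step_protocol(run_config(target_F = 0.5), factor = 2,
                             t_end = 10)
  expect_gt(res5$peak_rel, res$peak_rel)
  # no perturbation, no change
  flat <- pool_step_protocol(run_config(), factor = 1, t_end = 4)
  expect_lt(max(abs(flat$rel_w)), 1e-8)
})

test_that("emptying the pool depresses all synapses transiently", {
  res <- pool_step_protocol(run_config(), factor = 0, t_end = 60)
  expect_lt(min(res$rel_w), -0.01)
  # long-time recovery to the original fixed point
  expect_lt(max(abs(res$rel_w[nrow(res$rel_w), ])), 0.01)
})

test_that("slot steps give persistent homo- and transient heterosynaptic change", {
  res <- slot_step_protocol(t_end = 120)
  n <- length(res$hetero)
  # unstimulated synapses dip then recover toward zero
  expect_lt(res$peak_hetero, -0.03)
  expect_gt(res$hetero[n], -0.005)
  # stimulated synapses stay elevated (slots doubled at F = 0.5)
  expect_gt(res$homo[n], 0.9)
  # trough magnitude is near the constant-R analytic prediction
  expect_equal(res$peak_hetero, res$analytic_hetero, tolerance = 0.15)
  # recovery time constant close to 1/delta
  i0 <- which.min(res$hetero)
  tt <- res$trajectory$time[i0:n]; hh <- res$hetero[i0:n]
  keep <- hh < -1e-4
  tau <- -1 / coef(lm(log(-hh[keep]) ~ tt[keep]))[[2]]
  expect_lt(abs(tau - 14) / 14, 0.3)
  # identity perturbation does nothing
  flat <- slot_step_protocol(factor = 1, t_end = 4)
  expect_lt(max(abs(flat$rel_w)), 1e-8)
})

test_that("analytic heterosynaptic curve crosses zero at S' = S", {
  expect_equal(heterosynaptic_change_curve(200, F = 0.5, phi = 2.67, S = 200), 0,
               tolerance = 1e-10)
  # slot removal -> heterosynaptic potentiation; addition -> depression
  expect_gt(heterosynaptic_change_curve(150, 0.5, 2.67, 200), 0)
  expect_lt(heterosynaptic_change_curve(280, 0.5, 2.67, 200), 0)
  # the Fig.-5 default operating point
  expect_equal(heterosynaptic_change_curve(280, 0.5, 2.67, 200), -0.062,
               tolerance = 0.01)
  # a scarce pool amplifies the effect; a high filling fraction damps it
  sp <- seq(120, 300, 20)
  m1 <- abs(heterosynaptic_change_curve(sp, 0.5, 1.0, 200))
  m267 <- abs(heterosynaptic_change_curve(sp, 0.5, 2.67, 200))
  expect_true(all(m1[sp != 200] > m267[sp != 200]))
  m9 <- abs(heterosynaptic_change_curve(sp, 0.9, 2.67, 200))
  expect_true(all(m9[sp != 200] < m267[sp != 200]))
})

test_that("LTP waveforms hit their stated landmarks and stay continuous", {
  sp <- ltp_spec()
  expect_equal(ltp_alpha_factor(sp$onset, sp), 1)
  expect_equal(ltp_alpha_factor(sp$onset + 17 / 60, sp), 4)
  expect_equal(ltp_alpha_factor(sp$onset + 17 / 60 + 2, sp), 1)
  tgrid <- seq(0, 40, 1e-3)
  a <- ltp_alpha_factor(tgrid, sp)
  s <- ltp_slot_factor(tgrid, sp)
  expect_true(all(a > 0) && all(s > 0))
  # continuity: no jump larger than the local slope allows
  expect_lt(max(abs(diff(a))), 0.02)
  expect_lt(max(abs(diff(s))), 0.02)
  # peak and sustained slot factors follow the 2/3 surface-area scaling
  expect_equal(max(s), 5^(2 / 3), tolerance = 1e-6)
  expect_equal(ltp_slot_factor(60, sp), 2^(2 / 3), tolerance = 1e-3)
  # baseline before onset
  expect_true(all(a[tgrid < sp$onset] == 1))
  expect_true(all(s[tgrid < sp$onset] == 1))
})

test_that("LTP induction potentiates stimulated synapses and dips the rest", {
  res <- ltp_protocol(t_end = 12)
  expect_gt(res$peak_homo, 0.5)
  expect_lt(res$peak_hetero, 0)
  # occupancy never exceeds the (time-varying) slot count
  expect_true(all(res$trajectory$w <= res$trajectory$s + 1e-9))
  # small pool and low filling fraction: weaker homo peak, much deeper hetero
  res2 <- ltp_protocol(run_config(target_F = 0.5, target_phi = 1.0,
                                  slots = c(20, 40, 60, 80)), t_end = 12)
  expect_lt(res2$peak_homo, res$peak_homo)
  expect_lt(res2$peak_hetero, 3 * res$peak_hetero)
})

test_that("peak LTP grows and peak heterosynaptic LTD shrinks with pool size", {
  sw <- ltp_peak_sweep(phi_grid = c(1, 2.67, 5), F_set = c(0.5, 0.9),
                       t_end = 10)
  for (F in unique(sw$F)) {
    s <- sw[sw$F == F, ]
    s <- s[order(s$phi), ]
    expect_true(all(diff(s$peak_homo) > 0))
    expect_true(all(diff(abs(s$peak_hetero)) < 0))
  }
})

test_that("lognormal slot sampler hits its moments and scaling exactly", {
  s <- lognormal_slot_sampler(100, seed = 1)
  expect_equal(mean(s), 100, tolerance = 1e-12)
  expect_true(all(s > 0))
  # degenerate sd
  expect_equal(lognormal_slot_sampler(5, sd = 0), rep(100, 5))
  # the underlying variate has the requested mean and sd (law of large n)
  set.seed(2)
  big <- lognormal_slot_sampler(2e5, mean = 1, sd = 0.2,
                                target_mean_slots = 1)
  raw_sd <- sd(big / mean(big))
  expect_equal(raw_sd, 0.2, tolerance = 0.02)
  expect_error(lognormal_slot_sampler(0), "invalid")
  # occupancy CDFs for different filling fractions are horizontal shifts in
  # log space by the log of the F ratio
  s100 <- lognormal_slot_sampler(100, seed = 3)
  q5 <- quantile(log10(0.5 * s100), c(.1, .5, .9))
  q9 <- quantile(log10(0.9 * s100), c(.1, .5, .9))
  expect_equal(q9 - q5, rep(log10(0.9 / 0.5), 3), tolerance = 1e-12,
               ignore_attr = TRUE)
})
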