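# Shared fixtures: the 7-synapse slot group used for fluctuation analysis and
# the standard measured rates.
slots7 <- c(1, 2, 5, 10, 20, 50, 100)
beta_std <- 60 / 43   # (43 s)^-1 in min^-1
delta_std <- 1 / 14   # (14 min)^-1

# Independent Euler oracle for the full mass-action equations, written
# directly from the rate expressions (kept separate from integrate_model so
# the two can be compared).
euler_oracle <- function(w, p, s, rates, t_end, dt) {
  n <- round(t_end / dt)
  for (k in seq_len(n)) {
    bind <- rates$alpha * p * (s - w)
    unbind <- rates$beta * w
    w_new <- w + dt * (bind - unbind)
    p <- p + dt * (-rates$delta * p + rates$gamma + sum(unbind) - sum(bind))
    w <- w_new
  }
  list(w = w, p = p)
}
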