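test_that("long-term steady state matches its closed form and the ODE oracle", {
  r <- calibrate_rates(0.9, 2.67, 10000)
  ss <- long_term_steady_state(r, slots = rep(100, 100))
  expect_equal(ss$R_inf, 33030, tolerance = 1e-9)          # (1 + phi) F S
  expect_equal(ss$W_inf, sum(ss$w_inf), tolerance = 1e-12)
  expect_equal(ss$R_inf, r$gamma / r$delta + ss$F * 10000, tolerance = 1e-12)

  # gamma = 0: empty pool and empty synapses
  ss0 <- long_term_steady_state(rate_constants(1, 1, 0, 1), c(3, 7))
  expect_equal(ss0$p_inf, 0)
  expect_equal(ss0$w_inf, c(0, 0))

  # terminal state of a long Euler integration lands on the fixed point
  r2 <- calibrate_rates(0.6, 1.8, 60)
  s <- c(10, 20, 30)
  end <- euler_oracle(w = c(1, 1, 1), p = 5, s = s, r2, t_end = 600, dt = 0.005)
  ss2 <- long_term_steady_state(r2, s)
  expect_equal(end$w, ss2$w_inf, tolerance = 1e-6)
  expect_equal(end$p, ss2$p_inf, tolerance = 1e-6)

  expect_error(long_term_steady_state(rate_constants(1, 1, 1, 0), c(3)),
               "delta")
})

test_that("per-synapse occupancies keep the slot proportions", {
  r <- calibrate_rates(0.44, 3.1, 175)
  s <- c(12.5, 25, 50, 87.5)   # non-integer slots are allowed analytically
  ss <- long_term_steady_state(r, s)
  ratios <- ss$w_inf / s
  expect_lt(diff(range(ratios)), 1e-12)
  # multiplicative scaling: perturbing one rate rescales all w_inf by a
  # common factor
  for (fac in c(0.5, 2)) {
    r2 <- rate_constants(r$alpha, r$beta * fac, r$gamma, r$delta)
    f <- long_term_steady_state(r2, s)$w_inf / ss$w_inf
    expect_lt(diff(range(f)), 1e-12)
  }
})

test_that("fast equilibrium takes the physical root of the quadratic", {
  # rho = 0 limits: W* = min(R, S)
  expect_equal(fast_equilibrium(20000, 10000, 0)$W_star, 10000)
  expect_equal(fast_equilibrium(5000, 10000, 0)$F_star, 0.5)
  # fixed numeric example, cross-checked against a brute-force root and a
  # conserved-R (gamma = delta = 0) relaxation of the full equations
  fe <- fast_equilibrium(150, 100, 50)
  w_root <- uniroot(function(W) W^2 - W * (100 + 150 + 50) + 150 * 100,
                    c(0, 100), tol = 1e-12)$root
  expect_equal(fe$W_star, w_root, tolerance = 1e-9)
  expect_equal(fe$W_star, 63.40, tolerance = 1e-4)
  r <- rate_constants(alpha = 0.02, beta = 1, gamma = 0, delta = 0)  # rho = 50
  end <- euler_oracle(w = c(10, 10), p = 130, s = c(40, 60), r,
                      t_end = 200, dt = 0.002)
  expect_equal(sum(end$w), fe$W_star, tolerance = 1e-6)
  expect_equal(end$p, fe$p_star, tolerance = 1e-6)
  # per-synapse consistency: w* = p*/(p* + rho) * s
  fe2 <- fast_equilibrium(150, 100, 50, slots = c(40, 60))
  expect_equal(fe2$w_star,
               fe2$p_star / (fe2$p_star + 50) * c(40, 60), tolerance = 1e-9)
  expect_error(fast_equilibrium(-1, 10, 1), ">= 0")
})

test_that("the rejected '+' root always exceeds the receptor/slot bound", {
  set.seed(7)
  n <- 1e4
  R <- 10^runif(n, 0, 5); S <- 10^runif(n, 0, 5); rho <- 10^runif(n, -3, 4)
  b <- S + R + rho
  w_plus <- b / 2 + sqrt(b^2 / 4 - R * S)
  expect_true(all(w_plus > pmin(R, S)))
  # while the chosen root respects it
  w_minus <- vapply(seq_len(n),
                    function(i) fast_equilibrium(R[i], S[i], rho[i])$W_star,
                    numeric(1))
  expect_true(all(w_minus <= pmin(R, S) * (1 + 1e-12)))
})

test_that("fast filling fraction is monotone and approaches min(1, R/S)", {
  expect_equal(max_fast_filling_fraction(20000, 10000), 1)
  expect_equal(max_fast_filling_fraction(5000, 10000), 0.5)
  expect_equal(max_fast_filling_fraction(0, 10000), 0)
  expect_error(max_fast_filling_fraction(10, 0), "S")
  # rho -> 0+ limit of the quadratic root
  for (R in c(3000, 10000, 25000)) {
    f0 <- fast_equilibrium(R, 10000, 1e-9)$F_star
    expect_equal(f0, max_fast_filling_fraction(R, 10000), tolerance = 1e-5)
  }
  # monotone: non-increasing in rho, non-decreasing in R
  rho_grid <- 10^seq(-2, 4, length.out = 40)
  for (R in c(5000, 10000, 20000)) {
    f <- vapply(rho_grid, function(x) fast_equilibrium(R, 10000, x)$F_star,
                numeric(1))
    expect_true(all(diff(f) <= 1e-12))
  }
  R_grid <- seq(1000, 40000, length.out = 40)
  f <- vapply(R_grid, function(R) fast_equilibrium(R, 10000, 300)$F_star,
              numeric(1))
  expect_true(all(diff(f) >= -1e-12))
})

test_that("long- and short-term solutions coincide at the global fixed point", {
  for (F in c(0.5, 0.7, 0.9)) {
    r <- calibrate_rates(F, 2.67, 188)
    ss <- long_term_steady_state(r, slots7)
    fe <- fast_equilibrium(ss$R_inf, 188, r$beta / r$alpha)
    expect_equal(fe$F_star, F, tolerance = 1e-10)
  }
})

test_that("sensitivity to rho matches finite differences and flags R = S", {
  # analytic value at rho = 0, R = 2S
  expect_equal(fast_filling_sensitivity(20000, 10000, 0), -1e-4)
  # finite-difference agreement away from the singularity
  fd <- function(R, S, rho, h) {
    (fast_equilibrium(R, S, rho + h)$F_star -
       fast_equilibrium(R, S, max(rho - h, 0))$F_star) /
      (h + min(rho, h))
  }
  cases <- list(c(20000, 10000, 0), c(5000, 10000, 2), c(150, 100, 50),
                c(10000, 10000, 10), c(300, 1000, 0.5))
  for (cs in cases) {
    an <- fast_filling_sensitivity(cs[1], cs[2], cs[3])
    expect_equal(an, fd(cs[1], cs[2], cs[3], h = 1e-6 * max(1, cs[3])),
                 tolerance = 1e-4)
    expect_lt(an, 0)
  }
  # R < S branch uses |R - S|
  expect_equal(fast_filling_sensitivity(5000, 10000, 0),
               (1 - 15000 / 5000) / (2 * 10000), tolerance = 1e-12)
  # divergence at the matched point is explicit, not silent
  expect_warning(d <- fast_filling_sensitivity(10000, 10000, 0), "diverges")
  expect_identical(d, -Inf)
})
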