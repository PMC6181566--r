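#' Long-term steady state of the full model
#'
#' Closed-form fixed point of the mass-action system: the pool settles at
#' `p_inf = gamma / delta`; every synapse fills the same fraction
#' `F = 1/(1 + beta*delta/(alpha*gamma))` of its slots, so
#' `w_inf[i] = F * s_i`, `W_inf = F * S`, and the total receptor number is
#' `R_inf = p_inf + W_inf`. The fixed point is independent of the initial
#' condition; per-synapse efficacies are proportional to slot counts.
#'
#' @param rates a [rate_constants()] object; `delta` must be > 0.
#' @param slots numeric vector of per-synapse slot counts (>= 0; non-integer
#'   values are allowed in the deterministic model).
#' @return an object of class `"steady_state"`: list with `F`, `p_inf`,
#'   `w_inf` (per synapse), `W_inf`, `R_inf`, `slots`.
#' @export
#' @examples
#' r <- calibrate_rates(F = 0.9, phi = 2.67, S = 10000)
#' long_term_steady_state(r, slots = rep(100, 100))$R_inf  # 33030
long_term_steady_state <- function(rates, slots) {
  if (rates$delta <= 0) stop("'delta' must be > 0 for a finite pool fixed point")
  if (any(slots < 0)) stop("slot counts must be >= 0")
  F <- if (rates$gamma == 0) 0 else filling_fraction(rates)
  p_inf <- rates$gamma / rates$delta
  w_inf <- F * slots
  W_inf <- sum(w_inf)
  structure(list(F = F, p_inf = p_inf, w_inf = w_inf, W_inf = W_inf,
                 R_inf = p_inf + W_inf, slots = slots),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("Long-term steady state: N = %d synapses, S = %g slots\n",
              length(x$slots), sum(x$slots)))
  cat(sprintf("  F = %.6g, p_inf = %.6g, W_inf = %.6g, R_inf = %.6g\n",
              x$F, x$p_inf, x$W_inf, x$R_inf))
  invisible(x)
}

# Smaller root of W^2 - W*(S+R+rho) + R*S = 0, computed through the larger
# root (W- = RS / W+) so that no cancellation occurs when the discriminant is
# small, i.e. near R = S with rho -> 0.
fast_w_star <- function(R, S, rho) {
  b <- S + R + rho
  disc <- b * b / 4 - R * S         # >= rho*(...) >= 0 algebraically
  disc[disc < 0] <- 0               # guard tiny negative round-off
  w_plus <- b / 2 + sqrt(disc)
  ifelse(w_plus > 0, R * S / w_plus, 0)
}

#' Fast-timescale quasi-steady state at fixed total receptor number
#'
#' On timescales where externalization/internalization are negligible the
#' total receptor number `R = W + p` is conserved and binding/unbinding
#' equilibrate. The bound total solves the quadratic
#' `W*^2 - W*(S + R + rho) + R*S = 0` with `rho = beta/alpha`; the smaller
#' root is the physical one (the larger root exceeds `min(S, R)`). All
#' synapses share the short-term filling fraction `F* = W*/S`, so
#' `w*_i = F* s_i = p*/(p* + rho) * s_i` — redistribution is multiplicative.
#'
#' The root is evaluated through the numerically stable form
#' `W* = R*S / W+` to avoid cancellation near `R = S`, `rho -> 0`.
#'
#' @param R total receptor number (pool + bound), >= 0.
#' @param S total slot count, >= 0.
#' @param rho ratio `beta/alpha` >= 0, in receptor-count units.
#' @param slots optional per-synapse slot counts (summing to `S`) for which
#'   per-synapse `w_star` values are returned.
#' @return an object of class `"fast_equilibrium"`: list with `W_star`,
#'   `F_star`, `p_star`, and `w_star` (if `slots` given, else `NULL`).
#' @export
#' @examples
#' fast_equilibrium(R = 150, S = 100, rho = 50)$F_star  # ~0.634
fast_equilibrium <- function(R, S, rho, slots = NULL) {
  if (any(c(R, S, rho) < 0)) stop("'R', 'S' and 'rho' must be >= 0")
  if (!is.null(slots)) {
    if (any(slots < 0)) stop("slot counts must be >= 0")
    if (abs(sum(slots) - S) > 1e-9 * max(1, S))
      stop("'slots' must sum to 'S'")
  }
  W <- fast_w_star(R, S, rho)
  F_star <- if (S > 0) W / S else 0
  structure(list(W_star = W, F_star = F_star, p_star = R - W,
                 w_star = if (is.null(slots)) NULL else F_star * slots),
            class = "fast_equilibrium")
}

#' @export
print.fast_equilibrium <- function(x, ...) {
  cat(sprintf("Fast equilibrium (fixed R): W* = %.6g, F* = %.6g, p* = %.6g\n",
              x$W_star, x$F_star, x$p_star))
  invisible(x)
}

#' Maximum short-term filling fraction as rho -> 0
#'
#' With vanishing unbinding the bound total approaches `min(R, S)`:
#' with more receptors than slots every slot fills (`F* -> 1`), otherwise
#' `F*` approaches the receptor-to-slot ratio `R/S`.
#'
#' @param R total receptor number.
#' @param S total slot count (> 0).
#' @return `min(1, R/S)`.
#' @export
max_fast_filling_fraction <- function(R, S) {
  if (!is.finite(S) || S <= 0) stop("'S' must be > 0")
  if (R < 0) stop("'R' must be >= 0")
  pmin(1, R / S)
}

#' Sensitivity of the short-term filling fraction to rho
#'
#' Analytic derivative `dF*/drho`, always negative: raising unbinding
#' relative to binding empties slots. At `rho = 0` it reduces to
#' `(1/(2S)) * (1 - (R+S)/|R-S|)`, which diverges when the receptor number
#' exactly matches the slot number — the regime where the filling fraction
#' reacts most sensitively to changes in the binding/unbinding rates. At the
#' singular point (`R == S`, `rho == 0`) the function returns `-Inf` with a
#' warning rather than a finite number.
#'
#' @param R total receptor number.
#' @param S total slot count (> 0).
#' @param rho ratio beta/alpha, >= 0.
#' @return derivative of `F*` with respect to `rho` (<= 0, possibly `-Inf`).
#' @export
#' @examples
#' fast_filling_sensitivity(R = 20000, S = 10000, rho = 0)  # -1/S
fast_filling_sensitivity <- function(R, S, rho) {
  if (any(c(R, S, rho) < 0)) stop("'R', 'S' and 'rho' must be >= 0")
  if (S <= 0) stop("'S' must be > 0")
  if (rho == 0) {
    if (R == S) {
      warning("dF*/drho diverges at R = S, rho = 0")
      return(-Inf)
    }
    return((1 - (R + S) / abs(R - S)) / (2 * S))
  }
  b <- R + S + rho
  disc <- b * b / 4 - R * S
  (0.5 - (b / 4) / sqrt(disc)) / S
}
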