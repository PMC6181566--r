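---
title: "The receptor–slot competition model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The receptor–slot competition model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slotsim)
```

## The model

A local stretch of dendrite carries $N$ synapses. Synapse $i$ has $s_i$
postsynaptic *slots* (scaffold complexes that can each immobilize one
receptor) of which $w_i \le s_i$ are occupied; $w_i$ is the synaptic
efficacy. All synapses share a *pool* of $p$ freely diffusing surface
receptors. Receptors bind to empty slots with rate constant $\alpha$ (per
receptor per empty slot), unbind with rate $\beta$, are externalized into
the pool at rate $\gamma$ (receptors per minute), and internalized from the
pool with rate $\delta$. In the large-number limit,

$$\dot w_i = -\beta w_i + \alpha\, p\,(s_i - w_i), \qquad
  \dot p = -\delta p + \gamma + \sum_i \beta w_i
           - \sum_i \alpha\, p\,(s_i - w_i).$$

The mass-action binding term couples every synapse to every other through
$p$: this competition, not any explicit normalization rule, produces the
package's central phenomena. With $S = \sum_i s_i$ and $W = \sum_i w_i$:

* **Long-term fixed point.** $p_\infty = \gamma/\delta$ and every synapse
  fills the same fraction of its slots,
  $F = 1/(1 + \beta\delta/\alpha\gamma)$, so $w_{i,\infty} = F s_i$ and
  $R_\infty = p_\infty + FS = (1+\phi)FS$ where $\phi = p_\infty/W_\infty$
  is the relative pool size. Efficacy ratios equal slot ratios, and any
  rate change rescales all efficacies by a common factor (multiplicative
  scaling).
* **Fast quasi-steady state.** Binding/unbinding (seconds) is much faster
  than receptor turnover (tens of minutes), so on short timescales
  $R = W + p$ is conserved and $W$ settles at the smaller root of
  $W^2 - W(S + R + \rho) + RS = 0$, $\rho = \beta/\alpha$. The short-term
  filling fraction $F^* = W^*/S$ is again common to all synapses;
  $F^* \to \min\{1, R/S\}$ as $\rho \to 0$, and $\partial F^*/\partial\rho$
  diverges at $R = S$ — the system is most sensitive when receptors and
  slots are matched in number.
* **Slow accumulation.** Substituting the fast solution gives the reduced
  equation $\dot R = \gamma + \delta F^*(R) S - \delta R$, which relaxes to
  $R_\infty$ roughly exponentially with time constant $\approx 1/\delta$.

## Parameters, units, calibration

The canonical time unit is **minutes** everywhere; constructors accept a
`unit` argument because the measured constants mix seconds and minutes.
The defaults encode the experimentally motivated values:

| parameter | default | meaning |
|---|---|---|
| $\beta$ | $(43\,\mathrm{s})^{-1} = 60/43\ \mathrm{min}^{-1}$ | slot unbinding; 30 s dwell half-life |
| $\delta$ | $(14\,\mathrm{min})^{-1}$ | internalization; 10 min surface half-life |
| $\phi$ | 2.67 | relative pool size (72% mobile / 28% synaptic receptors) |
| $F$ | one of 0.5, 0.7, 0.9 | target filling fraction, set by hand |

$\alpha$ and $\gamma$ are rarely known directly; they are *calibrated* from
the targets: $\gamma = \delta\,\phi F S$ and
$\alpha = \beta / (\phi S (1-F))$. When $\alpha$ is instead held fixed and
only the pool size is targeted, $\gamma = \delta(S\phi - \beta/\alpha)$
with implied $F = 1 - \beta/(\alpha\phi S)$.

```{r calibration}
r <- calibrate_rates(F = 0.7, phi = 2.67, S = 188)
r
filling_fraction(r)   # round-trips to the target
```

Two notes on the published parameter tables that this package follows
deliberately. First, $\phi = 2.67$ is treated as the model parameter as
printed (although $0.72/0.28 = 2.571$), because every reference
configuration uses 2.67. Second, in the reference fit table that varies
$F$ at fixed $\phi$, the $\gamma$ column is inconsistent with
$\gamma = \delta\phi F S$ (which gives 17.9, 25.1, 33.9 rather than the
printed 12.1, 9.4, 6.7) while its $\alpha$ column matches the calibration
formula exactly, and the companion table that varies $\phi$ does match both
identities. The calibration equations are self-consistent, so this package
derives $\gamma$ from them and does not use that printed column.

## Numerical choices

**Quadratic root.** The physical root $W^*$ is the smaller one; the larger
root always exceeds $\min(S, R)$ and is rejected. Near $R = S$ with
$\rho \to 0$ the textbook form $\tfrac{b}{2} - \sqrt{b^2/4 - RS}$ cancels
catastrophically — exactly the regime where the sensitivity divergence
lives — so the root is evaluated as $W^* = RS / W^+$. The sensitivity
$\partial F^*/\partial\rho$ at the singular point $R=S$, $\rho=0$ returns
an explicit `-Inf` with a warning rather than a silently overflowed
number, and the $\rho=0$ formula uses $|R-S|$ so the slope is negative on
both sides.

**Integration.** The reference integrator is fixed-step forward Euler with
`dt = 0.005` min (0.3 s), at least an order of magnitude below the fastest
relaxation time $1/(\beta + \alpha p)$ under default parameters; sampling
defaults to 0.05 min. Convergence is first order, verified on a
step-halving ladder. Scheduled events (pool or slot steps) are applied
atomically at the step containing their time. A step that would push
$w_i$ outside $[0, s_i]$ by more than $10^{-6}$ aborts with advice to
lower `dt`; sub-tolerance overshoot is clipped with the excess returned to
the pool so receptors are never created or destroyed. Slot-shrink events
that strand bound receptors ($w_i > s_i$) likewise return the excess to
the pool — an extension choice, since the reference protocols never shrink
slots below occupancy. In waveform-driven runs the LTP protocols use
`dt = 0.002` min because the transient four-fold rise of $\alpha$ raises
the fastest rate accordingly.

**Stochastic simulation.** The integer model is simulated with the exact
Gillespie direct method over $2N + 2$ channels (bind/unbind per synapse,
externalize, internalize). Runs start at the rounded deterministic fixed
point ($w_i = \mathrm{round}(F s_i)$, $p = \mathrm{round}(\phi F S)$) —
the reference analysis reports steady-state fluctuations without stating
its initialization — and a 2 min burn-in is discarded before statistics.
The state is recorded on a fixed 1 s grid by carrying it between events,
which is unbiased for time averages and much finer than the slowest
relevant correlation time; the sampling interval for CV computation is a
declared convention, not a measured one. One seeded generator per run
makes every run bit-reproducible.

## Protocols

* **Pool step**: at 2 min the pool is rescaled (doubled or emptied);
  relative efficacy changes are identical across synapses at every instant
  and the transient peak matches the fast-equilibrium prediction at the
  stepped $R$.
* **Slot step**: slots of chosen synapses are doubled instantaneously
  (default: synapses 1 and 3 of a 20/40/60/80 group at $F = 0.5$). The
  unstimulated synapses dip by about $(F^* - F)/F$ (about $-6.2\%$ for the
  default) and recover with a fitted time constant close to $1/\delta$.
  The simulated trough is systematically a little shallower (about 10%)
  than the constant-$R$ analytic value because fast equilibration
  ($\tau \approx 0.4$ min here) and slow receptor influx overlap; the
  analytic curve assumes they do not.
* **Waveform LTP**: stimulated synapses get a binding-rate ramp (linear to
  $4\times$ in 17 s, linear back over 2 min — the reported CaMKII
  activation time course) and a slot-count waveform driven by spine
  volume: a sigmoidal rise to $5\times$ volume over 2 min followed by
  exponential decay to a sustained $2\times$ with a 5 min time constant,
  with slots scaling as volume$^{2/3}$ (surface area). "Sigmoidal" is
  implemented as a logistic pinned to its endpoints (midpoint at 1 min,
  exact baseline and peak at the rise boundaries), which keeps the
  composite waveform continuous; the named shape has no stated formula.
  The $\alpha$ ramp and the volume rise are taken to start simultaneously
  at onset. The per-synapse slot counts for the LTP figures are not stated
  in the source; the package reuses the 20/40/60/80 slot-step group with
  synapses 2 and 3 stimulated, recorded here as a convention.

```{r ltp, eval = FALSE}
sw <- ltp_peak_sweep(phi_grid = c(1, 2.67, 5), F_set = c(0.5, 0.9))
# peak homosynaptic LTP rises with phi; peak heterosynaptic LTD shrinks
```

## Synthetic slot counts

`lognormal_slot_sampler()` draws per-synapse slot counts from a lognormal
distribution parameterized by the mean (1.0) and standard deviation (0.2)
of the *variate itself* (the plain reading of the stated parameters; the
underlying normal parameters are solved from them), then rescales so the
sample mean is exactly the target (100 slots per synapse). This generator
reproduces the heavy-tailed spread of synaptic sizes used in the reference
demonstrations but none of the biological structure real dendrites add —
spatial gradients, correlated sizes of neighbouring spines, discreteness
of scaffold numbers — so tests passing on these fixtures validate the
kinetics, not any claim about real size distributions.

## Fluctuation analysis

Per-synapse CVs (sd/mean of the sampled bound count, in percent, after
burn-in) are averaged across runs *before* fitting, matching the stated
aggregation of the reference analysis; the fit is unweighted OLS of
$\log_{10}\mathrm{CV}$ on $\log_{10}(F s_i)$, as no weighting is stated.
Synapses with zero mean occupancy are flagged `NA` and excluded; the
1-slot synapse at $F = 0.5$ (mean 0.5) is included. An independent
binomial oracle — treating slots as independent with occupancy probability
$F$ — predicts $\mathrm{CV} = 100\sqrt{1-F}\,(Fs)^{-1/2}$, i.e. exponent
$-1/2$ and scale $100\sqrt{1-F}$; the shared pool induces weak
correlations that the fitted values track within a few percent. The
standard experiment is 10 runs × 30 simulated minutes over the 7-synapse
group (1, 2, 5, 10, 20, 50, 100 slots), which takes a few seconds.

## Problem sizes and limitations

The test suite integrates at most $10^4$ slots for minutes-to-hours of
simulated time and runs tens of Gillespie simulations of up to 30
simulated minutes — sizes chosen because every quantity of interest is
already converged there. Known limitations, inherited from the model
scope: no spatial diffusion along the dendrite (the pool is well mixed),
no receptor subunit diversity or state-dependent rates, no slot
production/degradation kinetics beyond imposed waveforms, and no stiff or
adaptive solver (the reference dynamics are non-stiff at the recommended
step sizes; the Euler scheme is kept as the reference integrator for
fidelity). The reduced accumulation equation approaches its fixed point
with an effective time constant slightly above $1/\delta$ (about 14.5 min
for the standard $S = 10^4$, $F = 0.9$, $\phi = 2.67$ setup, because
$F^*(R)$ still rises weakly near $R_\infty$), so reaching the fixed point
to within a single receptor out of 33 030 takes about 150 simulated
minutes rather than the two hours one might guess from $1/\delta$ alone.
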