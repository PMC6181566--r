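# slotsim

Synapses on a stretch of dendrite do not own their neurotransmitter
receptors: AMPA-type receptors hop between postsynaptic scaffold "slots"
and a shared pool of surface receptors on timescales of seconds to
minutes. `slotsim` implements the kinetic model of this competition — a
simulator and analysis toolkit for computational neuroscientists studying
fast synaptic normalization, heterosynaptic plasticity, and spontaneous
efficacy fluctuations.

Synapse *i* has *sᵢ* slots of which *wᵢ* are occupied (its efficacy); the
pool holds *p* receptors:

    ẇᵢ = −β wᵢ + α p (sᵢ − wᵢ)
    ṗ  = −δ p + γ + Σ β wᵢ − Σ α p (sᵢ − wᵢ)

with binding α, unbinding β, externalization γ, and internalization δ.
Binding/unbinding is fast (β ≈ (43 s)⁻¹) and turnover slow
(δ ≈ (14 min)⁻¹), which yields:

* a long-term fixed point with a common **filling fraction**
  F = 1/(1 + βδ/αγ) — efficacies proportional to slot counts, scaled
  multiplicatively by any rate change;
* a fast quasi-steady state at conserved total receptor number R, with
  W\* the physical root of W² − W(S+R+ρ) + RS = 0 (ρ = β/α), explaining
  transient heterosynaptic plasticity and its buffering by a large pool;
* a reduced one-dimensional accumulation law
  Ṙ = γ + δF\*(R)S − δR approaching R∞ = (1+φ)FS with time constant
  ≈ 1/δ (φ = pool-to-bound ratio);
* an exact Gillespie simulation of the integer model whose per-synapse
  efficacy fluctuations follow CV ≈ a·(F·s)^b with b ≈ −1/2.

The package covers rate calibration from experimental targets, both
closed-form steady states with sensitivity analysis, Euler integration
with event schedules and time-varying waveforms, plasticity protocols
(pool steps, slot steps, waveform-driven LTP), and CV power-law fitting.

## Worked example

```r
library(slotsim)

# Calibrate rates for filling fraction 0.9 and relative pool size 2.67
# over 180 slots, starting from the measured beta and delta
r <- calibrate_rates(F = 0.9, phi = 2.67, S = 180)
r
#> Rate constants (per minute):
#>   alpha = 0.0290335  (slot binding, per receptor x empty slot)
#>   beta  = 1.39535  (slot unbinding)
#>   gamma = 30.8957  (externalization, receptors/min)
#>   delta = 0.0714286  (internalization)
#>   derived: rho = beta/alpha = 48.06, F = 0.9

long_term_steady_state(r, slots = c(40, 60, 80))
#> Long-term steady state: N = 3 synapses, S = 180 slots
#>   F = 0.9, p_inf = 432.54, W_inf = 162, R_inf = 594.54

# Double the pool at t = 2 min: every synapse scales by the same factor
res <- pool_step_protocol(run_config(), factor = 2, t_end = 10)
res$peak_rel
#> [1] 0.052

# Fluctuations: 10 Gillespie runs x 30 min, 7 synapses (1..100 slots)
tab <- cv_experiment(c(0.9, 0.5), mode = "filling",
                     n_runs = 10, duration = 30, seed = 1)
tab[, c("F", "alpha", "gamma", "a", "b")]
#>     F   alpha gamma    a      b
#> 1 0.9 0.02780  32.3 31.0 -0.494
#> 2 0.5 0.00556  17.9 70.1 -0.501
```

The steady state shows 90% of slots filled with a pool 2.67× the bound
total. Doubling the pool only nudges efficacies up by ~5% — at F = 0.9
there are few empty slots to fill (at F = 0.5 the same step gives ~17%).
The CV fits say small synapses fluctuate hard (the scale factor `a` is
the CV in percent at one bound receptor) with exponent ≈ −1/2, and that a
high filling fraction damps fluctuations (31% vs 70% at unit occupancy).

A thin command-line wrapper with subcommands `steady-state`, `simulate`,
`accumulate`, `gillespie`, `fit-cv`, and `slot-sample` is installed at
`system.file("cli", "slotsim.R", package = "slotsim")`; see its header
for usage.

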