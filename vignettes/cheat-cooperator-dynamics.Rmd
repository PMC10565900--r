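---
title: "Equilibria and oscillations in cheat–cooperator dynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equilibria and oscillations in cheat–cooperator dynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cheatcycles)
```

## The question and the model

Populations of cooperators are exploitable by cheats. Empirically, the joint
dynamics range from fixation of one type, through stable coexistence, to
persistent cycles in the cheat proportion (famously, defective viral
particles in serial culture). `cheatcycles` implements a deliberately
minimal model family in which each candidate ingredient can be switched on
and off, so the origin of each dynamic regime can be isolated.

The core is a two-strain competitive Lotka–Volterra system. Cooperators
grow logistically at rate $r$ toward carrying capacity $K$; cheats grow at
$h$ times the cooperator rate, multiplied by two sigmoid modifiers bounded
in $[1-w, 1]$:

$$f_d(N_{co}) = 1 - a + \frac{a}{1 + e^{-s_d (N_{co} - t_d)}}, \qquad
  f_f(p_{co}) = 1 - b + \frac{b}{1 + e^{-s_f (p_{co} - t_f)}},$$

where $p_{co}$ is the cooperator proportion. $a$ and $b$ weight how much of
the cheat's advantage is gated by cooperator *density* and cooperator
*frequency* respectively; at $w = 0$ a modifier is identically 1. The
between-strain regulation weight is $\alpha = 1$ throughout: both strains
draw on the same resource, so every state on $N_{co} + N_{ch} = K$ is an
equilibrium and, in the undisturbed (chemostat) setting, all interior
trajectories converge to that line. Cheating never pays at the population
level; it only redistributes the shared capacity.

Three settings build on this core:

* **Chemostat**: plain integration. Always equilibrates.
* **Serial passage**: growth for $T_{grow}$ time units, then both densities
  divided by $D$ (exact arithmetic, no rounding), repeated. The bottleneck
  is what can reverse the direction of selection within a cycle.
* **Metapopulation**: $M$ subpopulations run the same growth law
  independently; each cycle they are integerized, partially mixed by
  $\mathrm{round}(F \cdot M)$ random pairwise pooling events, and
  bottlenecked with counts integerized again. Demographic noise at small
  counts drives oscillations *across* cycles.

## Default parameters, with units and why

| parameter | default | units | role |
|---|---|---|---|
| `r` | 1 | per time | cooperator intrinsic growth rate; sets the time scale |
| `K` | 10 | density | carrying capacity (equilibrium line at 10) |
| `alpha` | 1 | — | equal between-strain regulation |
| `h` | 2 | — | cheat growth advantage when both modifiers allow |
| `a`, `b` | 1, 0 | — | focal density-dependence-only setting |
| `s_d` | 2 | per density | density sigmoid steepness |
| `t_d` | `K/20` = 0.5 | density | density sigmoid threshold |
| `s_f` | 10 | — | frequency sigmoid steepness |
| `t_f` | 0.5 | — | frequency sigmoid threshold |
| `D` | 10 | — | dilution ratio |
| `Tgrow` | 10 | time | growth-phase duration (full regrowth at `r = 1`) |
| `n_cycles` | 200 | cycles | standard run length; statistics on cycles 51–200 |
| `M`, `K_sub`, `F` | 50, 50, 1 | — | metapopulation size, per-group capacity, mixing |

Two of these required genuine calibration, because the regime claims the
package tests are qualitative and the primary sources do not pin the values:

**The density threshold `t_d` must sit near the post-bottleneck density,
not near `K`.** Over one stabilized cycle the cooperator log-gain equals
$\ln D$. A cheat earns at most $h$ times the log-growth that happens while
$N_{co} > t_d$, which is about $h \ln(K / \max(t_d, K/D))$. With
$t_d = K/2$ that ceiling is $h \ln 2 \approx 0.7 h$, far below
$\ln 10 = 2.3$ for any plausible $h$: cheats are diluted to extinction
regardless of their frequency and *no* parameterization oscillates. With
$t_d$ at half the post-bottleneck density $K/D$, the early low-density phase
of each cycle penalizes cheats for a duration that grows with the cheat
proportion (more cheats at the bottleneck means fewer cooperators to climb
back past $t_d$), and the late high-density phase rewards them. The
bottleneck then alternates the direction of selection — the stated
oscillation mechanism — and a stable within-cycle oscillation appears at
$(a, b) = (1, 0)$, $D = 10$.

**The cheat advantage is `h = 2`.** With $h$ barely above 1 the
metapopulation's cheat relative fitness pins at 1.00 and the global series
is essentially red noise; the cross-cycle oscillation with a well-defined
10–20-cycle period, cheat fitness between 1 and 1.5, and high fitness
variance between groups appears when cheats can locally overexploit
cooperator-rich groups (a collapse-and-reseed cycle), which needs a
substantial advantage. $h = 2$ — cheats up to twice as fast, as for strongly
exploitative systems such as defective interfering particles — reproduces
all of those signatures at once. Both calibrations were made once, against
the qualitative regime structure, before any test expectation was frozen.

## The metapopulation life cycle and its stochasticity

Per growth cycle, in fixed order: grow all subpopulations → integerize →
mix → bottleneck (divide by $D$, integerize). Each mixing event draws two
distinct subpopulations uniformly, pools their counts per strain, and
replaces both with the integerized pooled average; a group can be drawn in
several events per cycle. RNG draws occur in a documented fixed order, so a
run is bit-reproducible from its seed.

Integerization defaults to *stochastic rounding* (floor plus a Bernoulli
draw on the fractional part). This is a considered deviation from
deterministic half-away-from-zero rounding, which is also available
(`integer_mode = "round"`): since all subpopulations start identical, a
deterministic rule keeps them identical forever — growth is deterministic,
mixing identical groups is a no-op, and the "stochastic" scenario would
contain no stochasticity at all. Stochastic rounding is exactly the
demographic sampling noise the scenario is meant to model, is unbiased, and
at the default scale ($K_{sub} = 50$, $D = 10$, so ~5 individuals per group
after each bottleneck) it produces local cheat extinction and reseeding
events, which are the engine of the cross-cycle oscillation. The third mode
(`"none"`) disables rounding entirely and, with $F = 0$, reduces every
subpopulation exactly to the serial-passage engine — the cross-engine oracle
used in the tests.

`K_sub = 50` itself is a choice (no stated value exists): large enough that
global extinction within 200 cycles is rare for $M \ge 50$, small enough
that count rounding matters. Increasing `K_sub` or `M` damps the
oscillation, which is itself one of the tested properties.

Relative fitness of cheats over one growth phase is
$\ln(ch_1/ch_0) / \ln(co_1/co_0)$, the ratio of realized Malthusian
parameters, computed on pre-integerization end densities; it is undefined
(and excluded from averages) when a strain is absent at either end or the
cooperator fold-change is zero. The per-cycle CV uses the $n-1$ standard
deviation over defined values. Because subpopulations where cheats die are
censored as undefined, the average over defined values can exceed 1 even
though pooled growth is zero-sum — this censoring is deliberate and is what
makes the statistic informative about the oscillating regime, where local
cheat extinctions are common.

## Periodicity statistics

`harmonic_regression` fits $y_t = c + A\sin(2\pi t/T) + B\cos(2\pi t/T)$ by
OLS for each candidate period $T$ (default integer periods 2–75, half the
standard 150-cycle analysis window), reports the amplitude
$\sqrt{A^2+B^2}$ with a 95% delta-method CI from the coefficient
covariance, and the peak period (smallest on ties). At period exactly 2 the
sine regressor vanishes at integer sampling; numerically null columns are
dropped from the design rather than fit (an early version returned
astronomically large garbage amplitudes at $T = 2$ for precisely this
reason). Constant series are flagged degenerate with zero amplitudes and
undefined CIs.

`dft_amplitude` mean-centers the series and returns
$\max_k 2|X_k|/L$ over nonzero frequencies, which equals the amplitude of a
pure tone with an integer number of periods in the window. The delta-method
CI construction and the grid resolution are this package's choices; nominal
95% coverage is verified by Monte Carlo in the test suite (≥ 90/100 on
noisy sinusoid fixtures).

`stabilized_amplitude` is $\max(p) - \min(p)$ over the within-cycle cheat
proportion series after a burn-in window (default: first 50 of 200 cycles),
sampled at the dense-output resolution `dt` rather than only at cycle ends,
because the oscillation unfolds within each growth phase. "Stabilized"
matters: at $h = 1$, and at the marginal frequency-only point where
$h(1-b) = 1$, the cheat proportion decays monotonically for hundreds of
cycles, so those neutrality tests measure after a much longer burn-in
(1800 of 2000 cycles) instead of calling a slow transient an oscillation.

## What the synthetic fixtures do and do not establish

`make_sine_series` generates $0.5 + A\sin(2\pi t/T) + \varepsilon$,
$\varepsilon \sim N(0, \sigma)$ — the oracle fixture for the analysis stack.
It establishes numerical correctness (exact recovery at $\sigma = 0$, CI
coverage at $\sigma > 0$) but deliberately does not mimic simulation
output: real cheat-proportion series are bounded, autocorrelated, and
non-sinusoidal. A green analysis-stack test therefore says the statistics
are computed correctly, not that the simulator oscillates — the regime
tests establish that separately, and only for the parameter region they
probe.

## Numerical choices

* Integrator: Dormand–Prince RK5(4), adaptive, rtol $10^{-8}$ / atol
  $10^{-10}$ (exposed), dense output by stepping exactly onto a fixed
  `dt = 0.01` grid. The stationarity probe (`find_equilibrium`) integrates
  at rtol $10^{-12}$ / atol $10^{-14}$ because it compares derivative norms
  against $10^{-10}$, at the error floor of the default tolerances.
* Negative solver undershoot is clipped to zero; output densities below
  $10^{-12}$ are floored to zero.
* Empty populations have derivative $(0, 0)$ and an undefined (NA) cheat
  proportion — never $0/0$.
* Ties in the peak period go to the smallest period; `round(F·M)` uses
  half-away-from-zero.
* Runs that lose both strains terminate early and are flagged
  (`extinct = TRUE`), never silently padded.

## Known limitations

* The mixing property "more mixing makes the dynamics less periodic" holds
  here only in its absolute form: the harmonic-regression peak signal falls
  steeply as $F$ grows, but the background falls with it, so the
  peak-to-background *ratio* does not decrease. In this parameterization
  mixing synchronizes the collapse-and-reseed cycle across groups (damping
  its amplitude) rather than de-cohering it. The corresponding acceptance
  check is left failing by design, with both forms asserted separately so
  the disagreement is visible.
* Stability of the chemostat equilibrium line is checked numerically, not
  analytically.
* No spatial arrangement of subpopulations, no more than two strains, and
  no optimization of experimental designs — the sweep utilities are meant
  as the raw material for such work.
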