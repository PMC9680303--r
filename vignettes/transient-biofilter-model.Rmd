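---
title: "A two-parameter transient model for packed-bed biofilters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-parameter transient model for packed-bed biofilters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biofiltr)
```

## The process and the model

A biofilter passes polluted air upward through a packed bed whose media
particles carry thin microbial biofilms. Pollutant (here, a volatile organic
compound such as benzene) partitions from the gas into the biofilm according
to Henry's law and is oxidized by the microorganisms. Detailed transient
models of this process couple gas-phase transport to diffusion-reaction in
the biofilm with Monod (or inhibitory) kinetics and oxygen limitation; they
predict well but need many parameters that industrial users rarely have.

This package implements the opposite trade-off: the simplest transient model
that still respects the physics.

**Gas phase.** The bed (height $H$) is treated as plug flow and discretized
into $n$ well-mixed segments of length $\Delta h = H/n$ (a tanks-in-series
cascade; $n = 10$ by default). For segment $i$ with gas concentration
$C_{g,i}$, superficial velocity $u_g$ and bed void fraction $\varepsilon$:

$$\varepsilon \frac{dC_{g,i}}{dt}
  = \frac{u_g}{\Delta h}\left(C_{g,i-1} - C_{g,i}\right)
  + D_e A_s \left.\frac{dC_l}{dx}\right|_{x=0}$$

where $D_e$ is the effective diffusivity of the pollutant in the biofilm and
$A_s$ the biofilm surface area per bed volume. Axial dispersion is neglected
by construction.

**Biofilm.** The biofilm is a planar slab of thickness $\delta$ with Henry
equilibrium at the gas interface, $C_l(0) = C_g / H'$, zero flux at the
support, and first-order degradation (the low-concentration limit of Monod
kinetics) with lumped rate constant

$$k_1 = \frac{\mu_m X}{Y K},$$

built from the maximum specific growth rate $\mu_m$, biofilm density $X$,
yield $Y$ and half-saturation constant $K$. The diffusion-reaction balance
$D_e C_l'' = k_1 C_l$ then has the closed form

$$C_l(x) = \frac{C_g}{H'\left(1 + e^{-2\delta\phi}\right)}
  \left(e^{\phi(x - 2\delta)} + e^{-\phi x}\right),
  \qquad \phi = \sqrt{k_1 / D_e},$$

whose interfacial gradient is
$\left.dC_l/dx\right|_{x=0} = -(\phi C_g / H')\tanh(\phi\delta)$ — linear in
the local gas concentration. That linearity is the whole trick: substituted
into the segment balance it yields a *linear* first-order ODE per segment,
and the model collapses to two constants,

$$\gamma_1 = \frac{H' u_g}{H' u_g + D_e A_s \phi \tanh(\delta\phi)\,\Delta h},
  \qquad
  \gamma_2 = \frac{H' u_g + D_e A_s \phi \tanh(\delta\phi)\,\Delta h}
                 {H' \varepsilon \Delta h}
           = \frac{u_g}{\gamma_1 \varepsilon \Delta h}.$$

$\gamma_1 \in (0,1)$ is the fraction of pollutant surviving one segment at
steady state; $\gamma_2$ (s$^{-1}$) is the per-segment transient rate
constant. A clean-bed segment fed a constant upstream concentration responds
as $C_{g,i}(t) = C_{g,i-1}\,\gamma_1 (1 - e^{-\gamma_2 t})$, the cascade
outlet is approximated by the product form
$C_{ge}(t) = C_{g0}\,\gamma_1^n (1 - e^{-\gamma_2 t})^n$, and the steady
state is exactly

$$C_{ge}^{ss} = C_{g0}\, \gamma_1^{\,n}.$$

The effective diffusivity comes from the standard empirical density
correlation
$D_e = D_w \left[1 - 0.43 X_v^{0.92} / (11.19 + 0.27 X_v^{0.99})\right]$
with $X_v$ in kg·m$^{-3}$.

## Parameters, units, and two conventions worth stating

All computation is in SI with time in seconds. Two conventions are easy to
get wrong and are therefore fixed explicitly:

* **Growth rate units.** $\mu_m$ is tabulated in the literature in
  h$^{-1}$; `compound_parameters()` accepts it that way by default
  (`mu_max_units = "1/h"`) and converts once at construction. Supplying a
  pre-converted s$^{-1}$ value produces a bit-identical object.
* **Biofilm density units.** The density correlation for $D_e$ consumes
  $X_v$ in kg·m$^{-3}$, while $k_1$ needs $X$ in g·m$^{-3}$ so units cancel
  against $K$ (g·m$^{-3}$); `first_order_rate()` converts internally
  ($X = 1000\,X_v$). With the bundled benzene constants this choice gives
  $k_1 \approx 2.18$ s$^{-1}$, $\phi\delta \approx 5.2$ and
  $\gamma_1 \approx 0.9785$ at an empty-bed residence time (EBRT) of 60 s —
  the chain that reproduces the bundled validation benchmark. An s$^{-1}$
  reading of the density would miss the benchmark by orders of magnitude.

Defaults: $n = 10$ segments (the benchmark's segmentation; configurable),
void fraction $\varepsilon = 0.35$ (a typical packed organic medium; the
benchmark does not report one). The choice of $\varepsilon$ is harmless for
every steady-state result: $\varepsilon$ enters only $\gamma_2$, so it
scales the transient time constant but provably not the $t \to \infty$
outlet — the suite asserts this. The flip side is that absolute transient
time axes should be read as conditional on $\varepsilon$; with the benchmark
bed, removal-relevant transients settle within a couple of minutes.

The short dual form of $\gamma_2$ is implemented as
$u_g / (\gamma_1 \varepsilon \Delta h)$ — the only reading consistent with
the full form and with dimensional analysis (s$^{-1}$) — and the equality of
the two forms is asserted to 1e-12 relative.

## Numerical choices

* $\tanh$ is evaluated directly; in double precision it saturates to exactly
  1 for arguments above ~20 without overflow, so deep-biofilm (high Thiele
  number) regimes are safe.
* The biofilm profile is evaluated in the grouping shown above, whose
  exponential arguments are all non-positive on $0 \le x \le \delta$; no
  overflow at large $\phi\delta$.
* `simulate_cascade()` advances each segment by its exact exponential
  solution with the upstream concentration frozen over a sub-step capped at
  $0.1/\gamma_2$. This scheme preserves the cascade fixed point
  $C_{g,i} = \gamma_1 C_{g,i-1}$ exactly (the simulated steady state matches
  $C_{g0}\gamma_1^n$ to ~1e-14 relative) and handles piecewise-constant
  inlet schedules by splitting sub-steps at breakpoints with state
  continuity.
* Output grids default to 500 points over the horizon; profile grids to 101
  points over the biofilm. Both are knobs, not physics.

**Product form vs chained cascade.** For $n > 1$ the closed-form product
$\gamma_1^n(1 - e^{-\gamma_2 t})^n$ is *not* the exact transient of the
series cascade (the exact solution convolves the segments); it is exact for
$n = 1$ and in both limits $t \to 0$ and $t \to \infty$. The test suite
quantifies the mid-transient gap against a stiff ODE integration of the full
cascade rather than hiding it: with the benzene parameters the two
trajectories agree at start and steady state and differ measurably
mid-transient. For time-resolved work with schedules use the integrator
(`solver: cascade`, the default); the analytic form is best used for its
steady state and for quick single-segment or settling-time estimates.

**Initial condition.** A clean bed (all segment concentrations zero) is
assumed unless a state is supplied; the per-segment exponential response
presumes exactly this.

## What the validation shows — and what it does not

`run_benzene_validation()` rebuilds the benchmark from raw constants only:
for each of six operating points (EBRT 60–186 s, inlets 0.13–0.37 g·m$^{-3}$)
it derives $u_g = H/\mathrm{EBRT}$, runs the chain above, and compares
$C_{g0}\gamma_1^{10}$ with the measured steady-state outlet. All six model
outlets agree with the previously reported predictions of this model after
rounding to the benchmark's two-decimal precision, and the percent errors
(computed from the rounded outlet, the benchmark's convention) match the
reported cells at five of six points. At EBRT 90 s the rounded
concentrations (0.14 vs 0.15 g·m$^{-3}$) give $-6.7\%$ while the benchmark
prints $-6.2\%$ — consistent with that cell having been computed from
unrounded values elsewhere; the package reports this cell but does not
assert it.

Limits of that evidence: the validation is steady-state only, for one
compound, on one bed. It says nothing about transient accuracy (no
time-resolved measurements are bundled), nothing about high-concentration
operation where first-order kinetics underestimates saturation effects
($C_l \ll K$ is the regime assumption; the benchmark inlets satisfy it),
and nothing about compounds whose degradation is oxygen-limited or
inhibited — those mechanisms are deliberately outside this model. Toluene
benchmark rows are bundled as comparison data, but toluene predictions
require user-supplied compound parameters.

## Synthetic inlet schedules

Real biofilter loads fluctuate with plant operation. `random_inlet_schedule()`
emulates this with uniform redraws on a user-chosen concentration band at a
fixed dwell time, under a mandatory seed. This reproduces the *structure* of
operational variability (piecewise-constant levels, abrupt steps), not its
statistics — real load series are autocorrelated and often diurnal. Passing
tests on such schedules demonstrates correct model mechanics (state
continuity, fixed-point tracking, reproducibility), not fidelity to any
measured load profile.

## A worked example

```{r example}
cfg <- read_run_config(system.file("extdata", "benzene.yaml",
                                   package = "biofiltr"))
log_derived_parameters(cfg)

run_benzene_validation()

res <- run_transient(cfg, t_end = 120)
res
```

## Known limitations

* First-order kinetics only; no Monod saturation, substrate inhibition,
  oxygen limitation, or multi-pollutant interaction.
* No axial dispersion; plug flow discretized as tanks-in-series.
* Biofilm parameters ($X_v$, $A_s$, $\delta$) are treated as knowns;
  in practice they usually need calibration against column data, and the
  package provides no fitting procedure.
* The product-form transient is approximate for $n > 1$ (see above).
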