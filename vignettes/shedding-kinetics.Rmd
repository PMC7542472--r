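---
title: "Multicompartment tumor growth and protein shedding kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multicompartment tumor growth and protein shedding kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumorshed)
```

## The problem

Whether a candidate protein biomarker becomes detectable in blood depends on
two coupled tissue-scale processes: how the proliferating and necrosing cell
populations of a vascularized tumor evolve, and how proteins released by
those populations reach the circulation. Secreted (extracellular, EC)
proteins are shed continuously by viable cells; the far larger class of
non-extracellular (non-EC) proteins — surface and intracellular — enters the
interstitium mainly when cells die. `tumorshed` simulates both, as a
function of tumor vascularization, so that the plasma trajectories of
hypothetical markers can be compared before any assay is built.

## The model

### Geometry

The perivascular microenvironment is idealized as a cylinder around a vessel
of mean diameter $d$ (core radius $\delta = d/2$). Viable tissue occupies a
necrotic cuff of width $\epsilon$ beyond the vessel wall — the oxygen
diffusion limit, about 100 µm — partitioned into $n = \epsilon/\sigma$
concentric shells of single-cell thickness $\sigma$ (10 µm), giving
$n = 10$ compartments by default. A cell at radial distance $r$ from the
wall belongs to compartment $\lceil r/\sigma \rceil$, and every
compartment's rates are evaluated at its radial midpoint
$s_i = \tfrac{2i-1}{2}\sigma$.

Shell subvolumes at vascular height $h$ are
$v_1 = \pi(\sigma+\delta)^2 h$ (the innermost shell subsumes the core — the
basis case of the shell recurrence; the alternative, excluding the
$\pi\delta^2 h$ core term, differs only by that additive constant) and
$v_i = \pi[(2i-1)\sigma^2 + 2\sigma\delta]h$ for $i \ge 2$; they sum exactly
to $\pi(n\sigma+\delta)^2 h$. Carrying capacities follow as
$K_i = v_i\,\rho\,p$ with cell density $\rho = 10^6$ cells/mm³ and packing
fraction $p = 0.2$. Vascularization is linear in time, $h_t = k_V t$, with
$h$ in millimetres — the unit that makes $v_i \rho p$ dimensionally
consistent — so capacities grow linearly: the model's "linear ceiling".

### Oxygen and rates

Oxygen decays exponentially with distance from the wall,
$C(r) = C_0\, 0.5^{\,r/r_{1/2}}$, with $C_0 = 16\%$ at the wall and
$r_{1/2} = 0.018$ mm. The half-distance is read as millimetres (18 µm):
that choice yields near-anoxia (≈ 0.4%) at the 100 µm cuff edge, which is
what makes the outer compartments net-necrotic in the first place.

Birth and death rates are linear in oxygen, anchored to in vitro
measurements at 1% and 20% O₂: birth from 7.8×10⁻⁴ to 8.2×10⁻³ day⁻¹,
death from 1.6×10⁻³ down to 0 day⁻¹. Each line is fit exactly through its
two measured points — the only reading that reproduces both printed
endpoints — and extrapolation beyond the measured span is linear, then
clamped at zero, since a negative birth or death rate is uninterpretable in
the difference equations. With the defaults this produces the
characteristic radial pattern: net growth $k_{G,i} = k_{B,i} - k_{D,i}$ is
positive near the vessel (+5.0×10⁻³ day⁻¹ in compartment 1) and negative at
the cuff (−1.1×10⁻³ day⁻¹ in compartment 10).

### Population dynamics

Populations advance by daily forward-Euler steps, a deliberate trade-off:
day-scale resolution suffices for multi-year simulations and keeps the
coupled system cheap enough for parameter scans. Each step applies, in a
fixed order that is part of the model definition (the results depend on
it): capacity update at the new day; births $k_B \Delta t P_i$ and deaths
$k_D \Delta t P_i$ (dead cells are cleared instantly and occupy no
capacity); an inner-to-outer overflow sweep in which a compartment's excess
over capacity is subtracted from it and added to its outward neighbour
(subtraction is forced by cell conservation; the outermost compartment is
uncapped, so overflow is never silently destroyed); and finally motility.

Motility is deterministic and fractional: each day 10% of a compartment
moves one step inward (toward oxygen) and 5% outward, boosted to 10%
outward when the donor outnumbers the receiver at least 10-fold or the
receiver is empty (so the growth front can advance). Fractions rather than
per-cell draws keep the model fully deterministic and reproducible; a
seeded stochastic mode would change no default result and is not provided.
The simulation seeds one cell in compartment 1 at $t = 0$, when $h_0 = 0$;
capacities take effect from day 1 so the seed is not instantly overflowed.

### Shedding and plasma kinetics

Compartment outflux is distance-weighted by the one-dimensional diffusivity
factor $w_i = 1/\sqrt{s_i}$ ($s_i$ in µm; the absolute scale of $w$ is
absorbed by the per-protein rates):

* EC ($EC=1$): $u_{i,t} = w_i\,\Phi\,P_{i,t}$ — proportional to the viable
  population;
* non-EC ($EC=0$): $u_{i,t} = w_i\,\Psi\,D_{i,t}/\Delta t$ — proportional
  to instantaneous death.

Plasma mass follows the one-compartment equation
$q_{t+1} = \sum_i u_{i,t}\Delta t + u_H \Delta t + (1 - k_E \Delta t) q_t$,
with first-order elimination $k_E = \ln 2 / t_{1/2}$ and a constant healthy
influx $u_H$ (zero in xenograft settings, where the tracked human protein
is non-endogenous). The initial plasma mass defaults to the healthy steady
state $u_H/k_E$, so a tumor-free run is exactly flat. Because plasma never
feeds back on the tumor, growth is simulated once and any number of
proteins are evaluated against the cached trajectory.

**Stability.** The daily Euler update is stable only for
$k_E \Delta t < 1$; the sensitivity range includes $t_{1/2} = 0.64$ day,
for which $k_E \approx 1.08$ day⁻¹. Rather than shrink the whole model's
grid, the plasma recurrence alone is sub-stepped: the day is split into the
smallest $m$ with $k_E \Delta t / m \le 0.5$ (here $m = 3$), with the
tumor outflux held constant within the day. Populations stay on the daily
grid. Requesting an unsplit unstable step is an error, not a warning.

## Parameters at a glance

| Parameter | Meaning | Default | Units |
|---|---|---|---|
| $\sigma$ | compartment (shell) thickness | 10 | µm |
| $d$ | mean vessel diameter ($\delta = d/2$) | 60 | µm |
| $\epsilon$ | necrotic cuff width | 100 | µm |
| $k_V$ | vascularization rate | 0.101 | day⁻¹ |
| $\rho$, $p$ | cell density, packing fraction | 10⁶, 0.2 | cells/mm³, — |
| $C_0$, $r_{1/2}$ | wall oxygen, half-distance | 16, 0.018 | %, mm |
| $k_B$, $k_D$ anchors | rates at 1% / 20% O₂ | [7.8e−4, 8.2e−3], [1.6e−3, 0] | day⁻¹ |
| motility | in / out / boosted out | 0.10 / 0.05 / 0.10 | day⁻¹ |
| $\Phi$, $\Psi$ | EC shedding, non-EC release | 4.5e−4 each | U cell⁻¹ day⁻¹, U/cell |
| $t_{1/2}$, $u_H$ | blood half-life, healthy influx | 6.4, 456 | day, U/day |
| $\Delta t$, $t_{end}$, $P_0$ | step, horizon, seed | 1, 4380, 1 | day, day, cell |

## A short run

```{r run}
cfg <- model_config()
traj <- simulate_growth(cfg, t_end = 1500)
tail(growth_summary(traj), 2)

sheds <- simulate_shedding_batch(traj, cfg$proteins)
sheds$EC_baseline
sheds$nonEC_baseline
```

The non-EC trajectory sits below the EC one and rises later: early tumors
are dominated by viable cells, so death-sourced shedding lags. The standard
experiment drivers — `grid_scan_growth()` for the $(k_V, C_0)$ validity
scan, `sensitivity_sweep()` for one-at-a-time sweeps,
`per_compartment_decomposition()` for stacked contributions, and
`protein_scan_envelopes()` for min/max dynamic-range envelopes over a
$(\Psi, t_{1/2})$ grid at each $u_H$ — all run on this in-series structure.
By the monotonicity of plasma mass in $\Psi$ and $t_{1/2}$, envelope bounds
coincide with the extreme-corner trajectories, which the implementation
verifies against the brute-force grid rather than assumes.

## Numerical and design choices

* **Populations are real-valued.** The seed $P_0 = 1$ is a convention, not
  a discretization; no rounding is applied anywhere.
* **Degenerate inputs.** $k_V = 0$ gives zero capacity forever (the seed is
  swept to the uncapped outermost compartment and decays); $C_0 \to 0$
  makes every compartment net-necrotic; both are legal runs, not errors.
  A radius outside $(0, \epsilon]$, a non-positive half-life, negative time
  and a non-integer $\epsilon/\sigma$ are errors.
* **Ties and sweeps.** Grid-scan selection takes, among valid cells, the
  smallest final population (selecting for more necrotic tumors), breaking
  ties toward smaller $k_V$ then smaller $C_0$, so selection is
  deterministic.
* **Validity cutoffs.** The scan's defaults (≥ 10⁷ cells and growth in all
  10 compartments at 12 years) are selection criteria, not assertions:
  under this implementation's strictly conservative overflow bookkeeping,
  the total capacity $\pi(n\sigma+\delta)^2 h_t \rho p$ at 12 years stays
  below 10⁷ cells for every $k_V \le 0.2$, so no pair in the default scan
  range clears the population cutoff. The `validity_criteria()` thresholds
  are therefore configurable.
* **Emergent timing.** With midpoint rate evaluation and conservative
  motility/overflow, the aggregate pre-capacity growth rate is bounded by
  $\max_i k_{G,i} \approx 5.0\times10^{-3}$ day⁻¹ (measured eigenvalue
  ≈ 4.2×10⁻³ day⁻¹), and the baseline run's exponential-to-capacity
  inflection, as detected by `detect_growth_inflection()` (trailing 30-day
  log-growth rate falling below half its early maximum), lands near
  11 years. Rate conventions that evaluate compartment 1 at the vessel wall
  instead of its midpoint would roughly match a ~6-year inflection; the
  midpoint convention is retained because it is the model's stated
  discretization.

## What the defaults do and do not emulate

The default configuration represents a slow-growing, heterogeneously
oxygenated solid tumor with histology-scale geometry (60 µm vessels, 100 µm
viable cuff) and ovarian-cancer-like shedding parameters (CA-125-scale
$\Phi$, 6.4-day half-life). It does not model: branching or 3-D vascular
networks (one cylindrical abstraction stands for all cross-sections);
density-dependent angiogenesis ($h_t$ is linear by design); interstitial
transport beyond the $1/\sqrt{s_i}$ attenuation; apoptosis as distinct from
necrosis; metastasis; or assay noise — plasma masses are in arbitrary units
U and are never converted to concentrations. Passing tests on this
generator therefore demonstrate internal consistency and the model's
qualitative mechanisms (capacity-limited slowdown, death-lagged non-EC
shedding, monotone parameter responses), not agreement with any particular
patient's kinetics.

## Problem sizes

Default runs use the 10-compartment geometry at daily resolution: a
12-year trajectory is 4380 steps and completes in well under a second, a
5×5 validity grid in seconds, and protein scans reuse one cached growth
trajectory per grid. Test-suite runs use shortened horizons (80–1500 days)
chosen to exercise every regime (pre-capacity growth, overflow onset,
plasma steady state) rather than full disease timelines.
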