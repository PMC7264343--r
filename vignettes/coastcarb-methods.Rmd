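---
title: "coastcarb: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{coastcarb: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coastcarb)
```

This vignette is the package's own account of its science: the models it
implements, the assumptions they rest on, the tunable parameters and
their provenance, what the synthetic generators do and do not emulate,
and the numerical choices that were genuinely open.

## 1. The speciation solver

The marine CO₂ system is resolved on the **total proton scale** at
surface pressure from any of three input pairs (DIC–TA, pCO₂–TA, pH–TA).
The alkalinity balance solved for pH is

TA = [HCO₃⁻] + 2[CO₃²⁻] + [B(OH)₄⁻] + [OH⁻] + phosphate and silicate
terms − [H⁺]F − [HSO₄⁻] − [HF],

with all equilibrium constants evaluated at the sample's temperature and
salinity and converted to the total scale through the sulfate and
fluoride equilibria where the published fit is on another scale.

**Constant set and why.** K₁/K₂ default to the Dickson & Millero (1987)
refit of the Mehrbach measurements; this is the literal constant choice
behind the package's reference numbers, and with it the canonical anchor
(pCO₂ = 395 µatm, TA = 2280 µmol kg⁻¹, S = 35, 18 °C) yields
DIC = 2038.59 µmol kg⁻¹. The Lueker et al. (2000) total-scale refit of
the same data is available through `carb_options(k1k2 = "lueker")` and
shifts that anchor by about +0.4 µmol kg⁻¹. The remaining constants
follow the conventional surface-water defaults (Weiss K₀, Dickson
boric-acid, Millero water, Uppström borate with Lee as an alternative,
Mucci aragonite solubility, calcium proportional to salinity). These
choices are deliberately configuration-switchable because the anchor
numbers are constant-set dependent at the few-tenths µmol kg⁻¹ level.

**Fugacity.** Henry's law is applied to the CO₂ *fugacity*: a pCO₂ input
is multiplied by the Weiss virial fugacity coefficient (≈ 0.9965 at
18 °C) before conversion to [CO₂aq], and the reported pCO₂ inverts the
same factor. This mirrors how the standard speciation programs treat a
pCO₂ input; without it the anchor DIC comes out ~0.65 µmol kg⁻¹ high.
`carb_options(fugacity = FALSE)` disables it. (The separate assumption
that atmospheric pCO₂ equals the dry mole fraction — no water-vapour
correction — is retained: the user supplies pCO₂atm directly.)

**Root finding.** pH is found with Brent's method (`uniroot`, a
safeguarded bisection/interpolation hybrid) on pH ∈ [2, 12] with
tolerance 10⁻⁹; the bracket endpoints are checked first and a
non-bracketing balance raises a convergence error. The solver is
deterministic; solved states close the alkalinity balance to well below
10⁻⁹ mol kg⁻¹. Nutrient (phosphate, silicate) alkalinity is included
whenever concentrations are supplied and must be supplied consistently
to both sides of any observed-vs-equilibrium comparison — the deviation
analysis does this internally.

## 2. Open vs closed systems, critical pH, Revelle factor

Two limiting regimes bracket the temperature behaviour of a surface
parcel: **closed** (no gas exchange: DIC and TA fixed, the acid–base
equilibrium shifts internally with the constants) and **open** (full
equilibrium with a fixed atmospheric pCO₂: DIC adjusts by exchange).
The gas-exchange decomposition
`term(T) = open(T) − closed(T) + open(T_ref)` attributes their
difference to exchange, anchored so all three curves agree at the
reference temperature (default 18 °C, configurable through the curve
functions and the `tempcurves` CLI flags). The framework's signature
predictions — pCO₂ and pH nearly invariant along an open-system
temperature gradient while DIC falls and Ω_arag rises with warming — are
enforced as property tests, including the quantitative cancellation
check that the open-system pH range is under 20 % of the closed-system
range on 5–25 °C.

Closed-system **temperature normalization** (`normalize_to_temperature`)
re-solves a sample at a common temperature (conventionally 25 °C) with
DIC and TA untouched, removing the thermodynamic part of the temperature
signal from pCO₂, pH and Ω.

The **critical pH**, −0.5·log₁₀(K₁K₂), is where [CO₂] = [CO₃²⁻] and the
system is least buffered. The package evaluates it at S = 35 by default;
the salinity underlying the reference values (7.70 at 3 °C, 7.60 at
10 °C, 7.35 at 30 °C with the default constants) is an adopted
convention, not a measured quantity, and the salinity argument is
exposed.

The **Revelle factor** is computed as a symmetric finite difference
(default ±1 µmol kg⁻¹ DIC; step-halving changes the estimate by < 0.5 %)
rather than by analytic buffer algebra. This matches the operational
definition RF = (ΔpCO₂/pCO₂)/(ΔDIC/DIC) directly and avoids committing
to one of the several analytic buffer formulations.

## 3. Air–sea exchange and the deviation analysis

Gas transfer uses the quadratic wind-speed relation
k = 0.251·W²·(Sc/660)^−0.5 (cm h⁻¹) with the CO₂-in-seawater Schmidt
number polynomial (defined for salinity 35; the salinity argument is
interface sugar). The flux law
F = 0.24·k·K₀·(pCO₂aq − pCO₂atm) (mmol m⁻² day⁻¹, efflux positive)
treats K₀·ΔpCO₂ in mol m⁻³ — the conventional ≈2.5 % density shortcut,
which is inside the uncertainty of k.

`deviation_analysis()` predicts, per bottle sample, the state the water
would have at equilibrium with atmospheric pCO₂ given its **measured**
TA (not a TA–salinity model), subtracts it from the observed state, and
correlates the DIC/Ω/pH deviations with the air–sea pCO₂ difference
(Pearson, pairwise-complete, no multiple-testing correction).
Atmospheric pCO₂ is a scalar per transect (default 395 µatm); seasonal
atmospheric cycles are out of scope.

## 4. The mixed-layer box model

A single homogeneous box of depth `mld_m` steps daily:

1. solve the carbonate system at (T, S, TA, DIC) of day *t*;
2. compute the air–sea increment from that day's pCO₂, add the
   prescribed biological (NCP, sink) and vertical-mixing (source)
   increments;
3. re-solve with the **same day's** T, S, TA and the new DIC (so all
   carbon parameters refer to one set of physical conditions);
4. advance T, S and TA (from salinity) at the start of the next day.

TA responds to salinity only, never to fluxes. The run is initialised at
atmospheric equilibrium, spun up for 180 days by replaying the forcing
days that cyclically precede day 1, and reports the spin-up-free
trajectory together with a companion series DIC_eq (pCO₂ relaxed to the
atmosphere each day: infinitely fast exchange).

**Numerical form of the air–sea step.** The increment is the closed-form
integral of the linearised relaxation over one day,
ΔDIC = −(ΔpCO₂/s)(1 − e^(−a·s)) with s = ∂pCO₂/∂DIC, which equals the
plain explicit-Euler increment −a·ΔpCO₂ to second order at realistic
winds (daily relaxation rate λ = a·s ≈ 0.01–0.03) but remains stable in
the instantaneous-equilibrium limit, where an explicit day step would
overshoot and diverge. This is what makes the "wind × 100 collapses DIC
onto DIC_eq" property testable at a 1-day step without sub-stepping.

**Parameters with units, defaults and provenance.**

| parameter | default | why |
|---|---|---|
| TA(S) slope, intercept | 50, 530 µmol kg⁻¹ | anchored so S = 35 → TA = 2280, the reference state; slope in the range of Atlantic margin TA–S fits |
| atmospheric pCO₂ | 395 µatm | the adopted annual-mean scalar; seasonally invariant |
| mixed-layer depth | 20 m | **an explicit modelling choice**: the flux law is per-area, the box per-volume, and the converting depth is otherwise unconstrained; e-folding times scale linearly with it |
| density | 1025 kg m⁻³ | constant surface value, adequate at model precision |
| C:Chl | 60 g g⁻¹ | fixed conversion from chlorophyll changes to carbon flux |
| winds | 7 (summer) / 10.5 (winter) m s⁻¹ | representative constants; 15-day linear ramps at the half-year transitions avoid step artefacts |
| winter mixing | 0.1 mmol m⁻³ day⁻¹ on the 155 days Oct 1 – Mar 4 (NWA); 0 (SAB) | scaling of vertical DIC gradients and diffusivity in the cold margin; negligible in summer |
| spin-up | 180 days | discarded from outputs |

NCP is derived from daily chlorophyll differences averaged by week,
× C:Chl / 12, re-interpolated to daily values anchored at each week's
middle day (so a week of steady 0.1 mg m⁻³ day⁻¹ growth maps to exactly
0.5 mmol C m⁻³ day⁻¹). All-gap weeks yield zero NCP with a warning.

The **e-folding experiment** pulses DIC into a steady box and times the
decay of excess pCO₂ to 1/e, interpolating linearly between daily
samples. With the defaults (wind 7 m s⁻¹, 20 m mixed layer) the
timescale is ≈ 88 days; it scales ∝ mld and ∝ W⁻², so the
often-quoted "about a month" corresponds to winter winds or a shallower
layer — the absolute number is a function of the unconstrained depth and
is therefore tested only through its scalings.

## 5. The synthetic generators: what a green test establishes

`make_transect()` emulates the *statistical structure* the analysis
assumes, not any real cruise: linear meridional SST/SSS gradients
(strong on the Atlantic/Gulf-of-Maine margin: SST 30 → 5 °C over
25–45 °N; weak in the California Current System), TA linear in salinity,
Gaussian measurement noise (σ = 2 µmol kg⁻¹ for TA and DIC, the nominal
bottle uncertainty), and — in `perturbed` mode — labelled additive
anomalies: upwelling (+70 µmol kg⁻¹ DIC, −4 °C, +12 µmol kg⁻¹ nitrate,
−25 % DO), river plume (−4 salinity, −20 DIC), bloom (−35 DIC, +18 %
DO). In `equilibrium` mode DIC is set exactly to its
atmospheric-equilibrium value given each sample's (noisy) TA, SST, SSS
and nutrients, which is what makes the zero-deviation test exact. The
gradient spans and anomaly amplitudes are emulation choices made once;
they are configurable but their defaults are not fitted to anything.

What a green test does **not** establish: realism of coastlines, water
masses, covariance between drivers (e.g., correlated SST–nutrient
structure within an upwelling filament), multi-depth structure, or any
real-cruise correlation value. Real-data patterns (maps, observed
correlation magnitudes) require the actual bottle archives and are out
of scope; the package tests that the *procedures* recover structure that
was injected by construction.

`make_forcing()` produces deterministic sinusoidal SST/SSS (NWA: SST
3–17 °C with a mid-February minimum, salinity highest in winter with a
summer minimum; SAB: 20–28 °C), the preset winds, a Gaussian spring
chlorophyll bloom sized so peak NCP ≈ 0.1 mmol C m⁻³ day⁻¹, and the NWA
winter-mixing window; optional seeded Gaussian noise is off by default.
Both generators save and restore the caller's RNG state, so they are
pure functions of their arguments and seed.

**North–south contrast.** With a single shared TA–S relation the warm
SAB box (SSS ≈ 36.2) carries ≈ 190 µmol kg⁻¹ more TA — and hence more
absolute DIC — than the cold NWA box. The meaningful, temperature-driven
contrast is therefore expressed in ratio/saturation space: SAB has a
lower DIC/TA ratio and higher Ω_arag than NWA on every model day, which
is also how the underlying framework phrases "low DIC in warm southern
waters" (relative to TA).

## 6. Degenerate inputs, tie-breaks, tolerances

* Solver preconditions: DIC, TA, pCO₂ > 0; DIC/TA ∈ (0.4, 1.3);
  temperature ∈ [−2, 40] °C, salinity ∈ (0, 42]; negative nutrients are
  domain errors. A non-bracketing alkalinity balance raises a
  convergence error rather than returning an extrapolated root.
* Deviation correlations need ≥ 3 complete rows and non-zero variance;
  otherwise `NA` (the all-at-equilibrium transect is the canonical
  zero-variance case).
* The e-folding search errors when the excess is non-decaying (wind → 0)
  or the horizon is exceeded; callers probing the closed-system limit
  should expect those errors, not a number.
* CSV exports round to 6 significant digits, making repeated seeded runs
  byte-identical.

## 7. Known limitations

Surface pressure only; no calcite Ω, no alternative pH scales, no
isotopes. One box, no horizontal advection; daily time step. The Schmidt
polynomial ignores salinity. The flux law's density shortcut and the
fixed 1025 kg m⁻³ conversion introduce ≈ 2–3 % unit-conversion bias,
well under gas-transfer uncertainty. Absolute e-folding times and box
amplitudes inherit the unconstrained mixed-layer depth; only their
scalings are meaningful.
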