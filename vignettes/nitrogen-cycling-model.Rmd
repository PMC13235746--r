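---
title: "A trait-based chemostat model of anaerobic nitrogen cycling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A trait-based chemostat model of anaerobic nitrogen cycling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omzniche)
```

## The model

`omzniche` simulates a virtual chemostat hosting the seven microbial
functional types that dominate anaerobic nitrogen cycling in oxygen
minimum zones: four partial denitrifier modules (NO₃⁻→NO₂⁻, NO₃⁻→N₂O,
NO₂⁻→N₂, N₂O→N₂), a complete denitrifier (NO₃⁻→N₂), a NO₂⁻→N₂O module,
and anammox bacteria (NH₄⁺ + NO₂⁻ → N₂). Five dissolved pools are tracked
— organic matter nitrogen (OM), NO₃⁻, NO₂⁻, N₂O and NH₄⁺ — all in μM of
nitrogen atoms (N₂O included, so its half-saturation constant in N units
applies directly). Rates are per day.

Each type requires two essential, non-substitutable resources: an electron
donor (OM for the heterotrophs, NH₄⁺ for anammox) and an electron acceptor.
Growth on each resource saturates (Monod), and the realized growth rate is
the Liebig minimum over the type's two resources; uptake of the
non-limiting resource is slaved to that rate, `V^r = μ/y`. Biomass is lost
and resources are exchanged at the dilution rate `a`:

$$\frac{1}{B_i}\frac{dB_i}{dt} = \mu_i - a, \qquad
\frac{dR_j}{dt} = a(s_j - R_j) + \sum_i E_{ij}B_i - \sum_i V^r_{ij}B_i.$$

Dependencies emerge from excretion: the NO₃⁻→NO₂⁻ reducer routes all
reduced acceptor nitrogen to NO₂⁻ (rate `μ₁/y₁,NO₃` per unit biomass), the
NO₃⁻→N₂O and NO₂⁻→N₂O modules likewise to N₂O, and every heterotroph
regenerates NH₄⁺ from the organic nitrogen it does not assimilate.
Terminal reducers and anammox produce N₂, which leaves the system — the
model's nitrogen loss. There is no partial branching within a type.

### The ammonium closure

The per-biomass NH₄⁺ excretion is taken as the nitrogen-balance closure
$e_{i5} = \mu_i\,(1/y_{i,\mathrm{OM}} - 1)$: OM-N uptake equals growth plus
NH₄⁺ release, exactly. Across the built-in yields (0.138–0.298) this makes
ammonium regeneration 70.2–86.2 % of the OM-N consumed, and hence of the OM
supply wherever OM is drawn down — consistent with the electron-balance
budgets from which the yields derive. An optional scalar multiplier
(`omz_traits(nh4_factor = )`) supports sensitivity runs. Whether a full
electron-balanced budget would differ at second order for specific C:N
values is unresolved; only the aggregate 70–86 % range is constrained.

## Parameters

The built-in trait table (`omz_traits()`) carries, for each of the 14 used
(type, resource) pairs, the maximum specific uptake rate `Vm` (mol
resource-N per mol biomass-N per day), half-saturation constant `K` (μM N)
and yield `y` (mol biomass-N per mol resource-N). Uptake kinetics are
shared across competing heterotroph modules (`Vm` = 1.377 on OM, 50.8 on
the nitrogen acceptors); the competitive structure comes from the yields,
which encode the redox energetics of each metabolism. Two trade-offs
organize everything:

* the NO₃⁻→NO₂⁻ reducer is the better OM competitor but the weaker NO₃⁻
  competitor than the NO₃⁻→N₂O reducer;
* recipients out-compete their feeders on OM
  (`R*` on OM: 0.0173 for the NO₂⁻→N₂ module vs 0.0240/0.0244 for the
  nitrate reducers), and anammox out-competes the heterotrophic nitrite
  reducers on NO₂⁻ (`R*` 0.035 vs 0.136/0.207) — the trait table's
  best-estimate affinity assumption.

The dilution rate is not part of the trait table; the default
`a = 0.04` d⁻¹ is recovered by inverting `R* = Ka/(yVm - a)` against the
table's subsistence column (e.g. for the nitrate reducer on OM,
`0.1·0.04/(0.15·1.377 − 0.04) = 0.02402 ≈ 0.024`). Because the printed
yields are rounded, the back-computed `R*` matches the tabulated column to
about 1 % on well-conditioned rows and to within 5 % everywhere — the
residual mismatch is rounding, not dynamics, and no attempt is made to
recover unrounded yields. `a` is exposed everywhere as a configuration
field.

```{r rstar}
rstar_table(omz_traits())
```

## Numerical choices

* **Integration.** The Liebig minimum makes the right-hand side continuous
  but non-smooth; no smoothing is applied. `deSolve::lsoda` with
  `rtol = 1e-10`, `atol = 1e-12` resolves the small competitive margins
  that decide several regime boundaries (the two nitrate reducers' OM
  subsistence concentrations differ by only 1.7 %, so exclusion rates can
  be a few 10⁻⁵ d⁻¹).
* **Equilibration.** `find_equilibrium()` integrates over doubling
  checkpoints (10³, 2·10³, … days, capped at 10⁶) until the scaled
  residual `max |dX/dt|/(|X| + 10⁻⁶)` drops below 10⁻⁸ — a derivative
  criterion, chosen over state differences to handle the slow transients
  near transcritical boundaries. Exhausted horizons are flagged
  `nonstationary`, never averaged.
* **Extinction and inoculation.** Biomasses below 10⁻⁹ μM N are pruned to
  zero between checkpoints; invaders are inoculated at 10⁻⁶ μM N (small
  enough not to perturb residents, large enough to clear the extinction
  floor). Types at exactly zero biomass are masked out of the dynamics:
  without the mask, solver roundoff seeds ~10⁻¹⁸ biomass that grows
  exponentially wherever the absent type could invade.
* **Conservation.** The excretion closure makes total nitrogen exactly
  budgeted: `d/dt(ΣR + ΣB) = a(Σs − ΣR − ΣB) − N₂ flux`, with N₂O a
  tracked pool rather than a loss. The residual is checked to 10⁻⁸
  relative along every test trajectory.
* **Ties.** Colimitation (potential growth rates equal within 10⁻⁹
  relative) is flagged and the lowest resource index reported.
* **Classification.** Gas fluxes below 10⁻¹⁰ μM N d⁻¹ count as zero when
  labeling nitrogen-loss regimes.

## Analysis layer

The resource-ratio toolkit operates on the same trait objects:
`rstar()`, `zngi()` (L-shaped isoclines; for anammox on the OM/NO₃⁻
*supply* axes a derived boundary is computed by bisection on the feeder's
equilibrium biomass against the threshold criterion), `consumption_vector()`
(reported as acceptor-N per OM-N, the yield ratio `y_OM/y_acceptor` — note
the orientation), `consortium_vector()` for feeder–recipient pairs, and
`feeder_threshold()`, the minimum feeder biomass `a·y_conv/μ_recipient`
sustaining a recipient.

The threshold formula, evaluated at recipient equilibrium (`μ = a`), is an
upper bound on the exact dynamical invasion boundary: for anammox invading
a lone NO₃⁻→NO₂⁻ reducer the formula gives 0.011 μM N of feeder biomass,
while direct simulation admits invasion from ~5·10⁻³ μM N (where ambient
NH₄⁺ first exceeds anammox's subsistence concentration). Both are exposed;
the test suite verifies they agree to within one step of a 0.05 μM N
supply transect.

`detect_multistability()` runs a canonical battery of assembly orders
(each type first, then the rest in index order, plus the all-at-once
start) and clusters the final states by persistent-set identity, then by
relative state distance (10⁻⁴). Orders in which a type arrives before its
substrate exists end in dead-ends that the washed-out type could still
invade; these are reported but only converged, mutually non-invasible
clusters count as alternative stable states. The battery is a pragmatic
stand-in for exhaustive order enumeration and can miss attractors whose
basin requires a specific *interior* arrival order (see Limitations).

## Supply-space sweeps

`supply_sweep()` maps community composition and nitrogen-loss pathway over
the OM × NO₃⁻ inflow plane from an "all present" start (every type at
10⁻³ μM N, resources at inflow). The default axes are 61 log-spaced points
over 0.01–30 μM N (`supply_axis()`): every subsistence concentration of
the trait set lies between 0.011 and 0.31 μM N, and the structure that
organizes the low-supply corner — persistence boundaries, feeder-biomass
thresholds, and the band where the N₂O producer persists below the biomass
that sustains the N₂O reducer — sits below 1 μM N, invisible to linear
spacing over this range. Axes store inflow concentrations `s_j`; multiply
by `a` for supply rates.

The sweep classifies each cell's loss regime from the equilibrium gas
fluxes: `conserved` (no gas), `N2_only`, `N2O_no_consumption` (the
accumulation-potential regime: steady-state N₂O is set by supply and
dilution, not by a consumer's subsistence concentration), and
`N2O_cycled_with_N2`. Bistable-aware sweeping (the order battery per cell,
~8× cost) is off by default.

Problem sizes used by the test suite: 21-point axes for the full-system
map, an 11×11 low-supply grid (OM 0.01–0.1, NO₃⁻ 0.05–0.5 μM N) for the
N₂O-accumulation regime, 16-point transects for the baseline system, and
20 random feasible supplies per type (fixed seed) for the closed-form
oracle comparison.

## What the model does and does not emulate

The chemostat idealization — constant dilution, steady resource supply,
perfect mixing — isolates the mechanistic interplay of competition and
metabolic dependency. Equilibrium maps therefore speak to time-averaged,
well-mixed conditions; they do not capture supply variability (which
generally broadens coexistence), spatial transport of intermediates,
aerobic metabolisms or nitrification at oxic interfaces, explicit NO, or
anammox's small NO₃⁻ release (neglected). Passing tests demonstrate the
internal consistency of this idealization against its own closed-form
theory, not fidelity to any particular ocean profile.

## Known limitations and observed behavior

* **Bistable wedge.** Over the supply-ratio band between the consortium
  vector `c₁₃` (≈5.12) and the N₂O producer's vector `c₂` (≈6.43) — and in
  the baseline coexistence wedge above it — the full system has
  alternative stable states: the {NO₃⁻→NO₂⁻, NO₂⁻→N₂} consortium (with
  anammox) versus N₂O-producer-containing communities. From the
  all-present start the consortium branch wins almost everywhere: the
  NO₃⁻→NO₂⁻ reducer's transient bloom floods the chemostat with NO₂⁻,
  establishing the nitrite reducer before anammox (capped by ammonium)
  could suppress it.
* **Niche breadths.** A consequence is that, measured on the default
  sweeps, anammox occupies a *slightly narrower* niche than the NO₂⁻→N₂
  denitrifier (≈0.15 vs ≈0.17 of converged cells): the nitrite reducer
  additionally holds a low-OM strip (OM inflow ≈0.03–0.06 μM N) where
  ammonium regeneration — 70–86 % of the tiny OM consumption — stays below
  anammox's NH₄⁺ subsistence concentration. With only the NO₃⁻→NO₂⁻
  reducer as source, excreted NO₂⁻:NH₄⁺ is ~16:1 against anammox's ~1.2:1
  demand, so anammox near its own invasion boundary is always
  ammonium-limited and cannot monopolize nitrite there. A broader anammox
  niche emerges only on the N₂O-producer branch of the bistable wedge,
  which the all-present initial condition does not select; conclusions
  about anammox's relative niche breadth are therefore assembly-history
  dependent in this model.
* **Weakest competitor.** The NO₂⁻→N₂O module is excluded everywhere on
  the default maps: wherever enough NO₂⁻ accumulates to support it, the
  NO₂⁻→N₂ module or anammox (both with lower NO₂⁻ subsistence) also
  invades and starves it.
* The complete denitrifier dominates the NO₃⁻-limited half-plane (supply
  ratio below its consumption vector ≈5.3) thanks to the lowest NO₃⁻
  subsistence concentration, and is squeezed out as NO₃⁻ supply rises.
* Near-threshold cells converge slowly (exclusion rates down to
  ~3·10⁻⁵ d⁻¹); the checkpoint doubling handles them but full-map sweeps
  spend most of their time there.
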