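# omzniche

Trait-based consumer–resource modeling of anaerobic marine nitrogen
cycling.

In the anoxic cores of oxygen minimum zones, bioavailable nitrogen is lost
as gas by two guilds of anaerobic microbes: heterotrophic denitrifiers that
respire nitrogen oxides while oxidizing organic matter, usually carrying
out only part of the reduction chain NO₃⁻ → NO₂⁻ → N₂O → N₂, and
chemoautotrophic anammox bacteria that combine NH₄⁺ with NO₂⁻ to make N₂.
These populations compete for shared substrates while simultaneously
feeding each other: the excreted intermediate of one module (NO₂⁻, N₂O,
NH₄⁺) is an essential substrate for another. `omzniche` implements a
chemostat consumer–resource model of this community — seven functional
types on five resources — for microbial ecologists and biogeochemical
modelers who want to ask where in (organic matter, nitrate) supply space
each community assembles, which nitrogen-loss pathway (N₂ vs N₂O) it
expresses, and when the outcome depends on arrival order.

## Model

Biomasses `B_i` (μM N) and resource concentrations `R_j` (μM N) follow

    dB_i/dt = (μ_i − a) B_i
    dR_j/dt = a (s_j − R_j) + Σ_i E_ij B_i − Σ_i V^r_ij B_i

with dilution rate `a` (default 0.04 d⁻¹) and inflow concentrations `s_j`
(only OM and NO₃⁻ by default). Growth on each essential resource saturates
as `μ_ij = y_ij V^m_ij R_j/(R_j + K_ij)`; the realized rate is the Liebig
minimum `μ_i = min_j μ_ij`, and uptake of every essential resource is
slaved to it, `V^r_ij = μ_i / y_ij`. Excretion `E_ij` routes all reduced
acceptor nitrogen to the product pool (NO₂⁻ for the NO₃⁻→NO₂⁻ reducer, N₂O
for the incomplete reducers) and regenerates NH₄⁺ from the non-assimilated
share of organic nitrogen, `e_i5 = μ_i (1/y_i,OM − 1)`, i.e. 70–86 % of the
OM supply across the built-in yields. Terminal reduction steps and anammox
release N₂, the model's nitrogen loss.

The analysis layer provides the standard resource-ratio toolkit: the
subsistence concentration `R* = K a/(y V^m − a)`, L-shaped zero net growth
isoclines, consumption vectors `c_i = y_i,OM / y_i,acceptor` and their
feeder–recipient consortium extension `c_fr = c_f/(1 + c_f/c_r)`, the
minimum feeder biomass `a y_f,conv / μ_r` that sustains a recipient,
invasion analysis, assembly-order experiments with multistability
detection, and 2-D supply-space sweeps that classify community composition
and nitrogen-loss regimes.

## Worked example

```r
library(omzniche)

traits <- omz_traits()          # built-in trait table, a = 0.04 / d
rstar(traits, "B1", "OM")       # 0.02402 uM N
rstar(traits, "B1", "NO3")      # 0.3084  uM N

# a lone NO3->NO2 reducer in a chemostat fed 1 uM OM-N and 30 uM NO3-N
eq <- find_equilibrium(traits, supply_spec(OM = 1, NO3 = 30), subsystem = 1)
eq
#> Equilibrium: converged at t = 1000 d (residual 8.67e-16 )
#> Persistent: B1
#> Limiting resources: B1:OM
#>     B1     B2     B3     B4     B5     B6     B7
#> 0.1464 0.0000 0.0000 0.0000 0.0000 0.0000 0.0000
#>       OM      NO3      NO2      N2O      NH4
#>  0.02402 16.69000 13.31000  0.00000  0.82960
```

OM is drawn down to the subsistence concentration 0.024 μM N, biomass
settles at `y (s − R*) = 0.146` μM N, and the 13.3 μM N of accumulated
NO₂⁻ is the niche this feeder opens for nitrite consumers. Anammox can
invade because the feeder biomass exceeds the threshold
`feeder_threshold(traits, 1, 5)` = 0.011 μM N:

```r
invasion_rate(traits, eq, 5)
#> Invasion of B5 into { B1 }: mu = 0.42815 /d -> SUCCESS

map <- supply_sweep(traits, subsystem = c(1, 2),
                    s1 = c(1, 3, 6), s2 = 30)
map$cells[, c("s1", "s2", "community", "nloss")]
#>   s1 s2 community              nloss
#> 1  1 30        B1          conserved
#> 2  3 30     B1+B2 N2O_no_consumption
#> 3  6 30        B2 N2O_no_consumption
```

Along a supply-ratio transect the classical succession appears: the
OM-specialist NO₃⁻→NO₂⁻ reducer alone, coexistence, then the N₂O producer
alone — and nitrogen loss switches on only once the N₂O producer persists.
Full seven-type maps are produced the same way with the default log-spaced
axes (`supply_axis()`), and `detect_multistability()` exposes the
priority-effect band where the {B1,B3} consortium and the N₂O producer are
alternative stable states.

A thin command-line wrapper over the same functions is installed at
`inst/cli/omzniche` (subcommands `rstar`, `fixture`, `simulate`, `sweep`,
`assembly`).

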