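# cstbr

Process analytics for **c**ontinuous **st**irred-tank **b**iogas
**r**eactors under trace-element limitation.

Anaerobic digesters need trace-element (TE) micronutrients — Co, Ni, Se, W
— as enzyme cofactors for acetogenesis and methanogenesis. When
supplementation of a required element stops, it washes out on the hydraulic
time scale, methane-forming kinetics slow, volatile fatty acids (VFAs)
accumulate (propionate, then acetate, then butyrate), and the process
fails. `cstbr` is for process engineers and microbial ecologists who
monitor such reactors: it turns continuous gas-meter/CH₄-sensor streams
into a per-day early-warning statistic that reacts *before* VFA
accumulation is visible in weekly samples, and it bundles the washout
model, the stoichiometric bookkeeping and the community statistics that a
TE-depletion study needs.

The core statistic: each daily feeding cycle's cumulative methane $y(t)$ is
fitted with a continuous two-segment line

$$y = b_0 + b_1 t + b_2 (t-c)_+ ,$$

minimising SSE over the knot $c$ (grid search over sample times plus
golden-section refinement). The knot — the time after feeding when methane
production falls to its residual level — is trended day by day; an alarm
fires when its trailing drift slope exceeds 15 min/day for three
consecutive days or the knot passes 1200 min. Around the statistic sit:

* **Gas processing** — sensor fusion, normalisation to dry normal
  conditions (0 °C, 1013.25 hPa, Magnus water-vapour correction), running
  means, cycle segmentation, yields per gCOD.
* **TE washout** — ideal-CSTR closed form $C(t)=C_{in}+(C_0-C_{in})e^{-t/HRT}$
  with step removals and pulse doses, an ODE cross-check, unit conversions
  (nM ↔ ng/gCOD), and exact back-solving of unrecorded pulse magnitudes.
* **Substrate accounting** — Buswell stoichiometry (350 mL CH₄/gCOD), VFA
  mM ↔ mg/L conversions, substrate TE contribution totals with
  round-half-even significant figures, COD balance closure.
* **Community statistics** — Hill diversity/evenness (¹D, ¹E = ¹D/⁰D),
  Hellinger standardisation, Bray–Curtis NMDS, k-means with
  Calinski–Harabasz model-order selection, Dufrêne–Legendre indicator
  genera with permutation p-values, cluster ANOVA; ASV tables live in a
  `SummarizedExperiment`-backed container.
* **Synthetic digester** — a seeded COD-pool simulator (Rcpp core) that
  reproduces the study conditions (4 L, HRT 30 d, OLR 1.7 gCOD/L/d,
  depletion day 206) with cascade-shaped daily methane curves, TE-limited
  syntrophy, progressive VFA accumulation, a pH proxy and drifting
  Dirichlet-multinomial ASV tables, plus a COD ledger that balances to
  1e-6. Every pipeline stage is testable without external data.

## Worked example

```r
library(cstbr)

cfg    <- simConfig(reactors = c("R_ctrl", "R_Ni"), horizonDays = 280)
bundle <- simulateDigester(cfg, seed = 1)
simEvents(bundle)
#>        reactor           event day
#> R_Ni.1    R_Ni propionateOnset 227
#> R_Ni.2    R_Ni    acetateOnset 238
#> R_Ni.3    R_Ni   butyrateOnset 240
#> R_Ni.4    R_Ni         failure 252
```

The Ni-depleted reactor starts accumulating propionate on day 227 (three
weeks after supplementation stopped on day 206); the control rows are all
`NA`. The kinetics module sees it coming ten days earlier:

```r
trend <- breakpointKinetics(bundle@gas[["R_Ni"]], startDay = 180)
trend
#> BreakpointTrend: 100 days (180 .. 279), knots 94 .. 1325 min | ALARM on day 217
alarmDay(breakpointKinetics(bundle@gas[["R_ctrl"]], startDay = 180))
#> [1] NA
```

The washout model explains why: the supplemented Ni fraction has fallen
from 0.13 nM to

```r
ni <- teHistories(cfg, "R_Ni")[["Ni"]]
round(concentrationAt(ni, c(229, 257)), 2)
#> [1] 0.06 0.02
```

by days 229 and 257. Steady-state yield bookkeeping:

```r
dailyYield(1430, feedingSchedule(0))   # mL CH4 per gCOD fed
#> [1] 210.2941
codMethaneVolume(sigfig = 3)           # stoichiometric ceiling, mL/gCOD
#> [1] 350
```

`runPipeline(cfg, seed = 1)` runs every stage (kinetics, washout,
substrate, community) and `writeReport()` emits a JSON + text report.

## Package layout

```
R/                  S4 classes, generics and the analysis modules
src/sim_core.cpp    minute-resolution COD-pool simulator core
tests/testthat/     unit, property and acceptance suites
vignettes/          methods vignette (models, assumptions, calibration)
scripts/            acceptance script
```
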