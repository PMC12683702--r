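# reefstates

Coupled coral–macroalgae dynamics, management interventions and
decision analysis on networks of reefs.

Coral reefs can be locally *bistable*: at the same parameter values a
reef may settle into either a coral-dominated or a macroalgal-dominated
state, depending on its history. Which state wins is controlled largely
by herbivore grazing (a sea-based pressure, lowered by fishing) and
coral mortality (raised by sedimentation, a land-based pressure), while
larval and gamete dispersal couples the fates of neighbouring reefs
into one network. `reefstates` is for spatial ecologists and
conservation planners who want to ask, on such a network: *which
management lever — expanding fishery closures, improving water quality,
or both — best keeps coral cover high, and is that choice robust to
what we don't know about grazing?*

## The model

Each reef `i` carries macroalgae `M_i`, coral `C_i` and free space
`F_i = 1 − M_i − C_i`, with dynamics

    dM_i/dt = a·M_i·C_i − g_i·M_i/(M_i + F_i) + Σ_j γ·n_ij·F_i·M_j
    dC_i/dt = Σ_j r·k_ij·F_i·C_j − a·M_i·C_i − d_i·C_i

where `a` is macroalgal overgrowth of coral, `g_i` herbivore grazing
(spread indiscriminately over macroalgae and free space), `γ` and `r`
gamete/larval production, `n_ij`, `k_ij` dispersal settlement rates,
and `d_i` coral mortality. An isolated reef passes from macroalgal
dominance through bistability to coral dominance as `g` rises; the
three grazing scenarios (median g = 0.1 / 0.3 / 0.5) represent exactly
those regimes.

On top of the simulator the package provides:

* a **synthetic seascape generator** (clustered reefs, fishery
  closures, skewed herbivore densities, spatially autocorrelated
  sediment, distance-decay dispersal kernels with PLD-dependent range)
  so the full analysis runs without any sensitive survey data;
* a **management engine**: closure expansion by radius (2 km within
  fishing grounds / 5 km across them), water-quality improvement
  (percent reductions of coral mortality, network-wide or scattered),
  and their combinations;
* **metrics**: healthy-reef counts (final coral cover > 30%),
  percentage-point deltas against baseline, net larval migration,
  connectivity-graph diagnostics;
* an **EVPI decision analysis** ("average of the best" minus "best of
  the averages") quantifying whether resolving the grazing-scenario
  uncertainty would change the best intervention;
* **sensitivity grids** over overgrowth, median mortality, larval
  duration and initial conditions.

## Worked example

```r
library(reefstates)

reefs <- generate_seascape(seed = 1)            # 75 reefs, 21 in closures
K <- coral_connectivity(reefs, seed = 1)        # pooled over PLD 10-130 d
N <- macroalgal_connectivity(reefs, seed = 501) # 5-day gamete kernel

grid <- run_grid(reefs, K, N)   # 3 scenarios x (baseline + 6 arms)
compute_evpi(grid$metrics)
```

```
Healthy-reef counts by intervention and grazing scenario
                         low medium high avg across scenarios
M1-2km                     0   16.0 43.0              19.6667
M1-5km                     0   15.0 42.0              19.0000
M2-10%                     0   25.0 51.0              25.3333
M2-25%                     0   53.0 68.0              40.3333
M3-2km+10%                 0   25.0 51.0              25.3333
M3-2km+25%                 0   55.0 66.0              40.3333
avg across interventions   0   31.5 53.5

average of the best:  41.0000
best of the averages: 40.3333
EVPI:                 0.6667
```

Reading this: under low grazing the whole synthetic network collapses
to macroalgae regardless of management; under medium and high grazing a
growing share of reefs holds > 30% coral, water-quality arms outperform
closure expansion at equal "magnitude", and the strongest combined arm
(M3-2km+25%) is best or near-best everywhere. The EVPI of 0.67 reefs
says that knowing the true grazing scenario in advance would improve
the expected healthy-reef count by less than one reef over just picking
the best-on-average intervention — the decision is robust to that
uncertainty. (These numbers describe the bundled synthetic seascape,
not any real reef system.)

`tidy(grid)` returns the long per-reef results,
`autoplot(grid)` the intervention-effect boxplots, and
`water_quality_sweep()`, `sensitivity_grid()`, `run_pipeline()` drive
the larger experiments.

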