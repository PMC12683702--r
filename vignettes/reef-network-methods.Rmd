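---
title: "Benthic dynamics, management interventions and decision analysis on a reef network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benthic dynamics, management interventions and decision analysis on a reef network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(reefstates)
library(dplyr)
```

## The model

Each reef $i$ in a network of $n$ reefs carries three benthic cover
fractions: macroalgae $M_i$, coral $C_i$, and free space
$F_i = 1 - M_i - C_i$ (turf, crustose coralline algae and other
settleable substrate). Their dynamics couple local competition with
propagule exchange across the network:

$$\frac{dM_i}{dt} = a M_i C_i \;-\; \frac{g_i M_i}{M_i + F_i}
  \;+\; \sum_j \gamma\, n_{ij} F_i M_j,$$

$$\frac{dC_i}{dt} = \sum_j r\, k_{ij} F_i C_j \;-\; a M_i C_i \;-\; d_i C_i.$$

Macroalgae overgrow mature coral at rate $a$, are removed by herbivores
grazing indiscriminately over macroalgae and free space (the
$g_i M_i/(M_i+F_i)$ term), and recruit as gametes produced at rate
$\gamma$ at every reef $j$ settle on local free space at rate $n_{ij}$.
Coral recruits from the network larval pool (production rate $r$,
settlement rates $k_{ij}$), and loses cover to overgrowth and to
mortality $d_i$. Free space is algebraically eliminated, so cover
conservation holds exactly by construction and only $2n$ equations are
integrated.

An isolated reef of this form is the classic grazing-bistability system:
below a grazing threshold only the macroalgal state is stable, above a
second threshold only the coral state, and in between both coexist and
history decides the outcome. The three named grazing scenarios (`low`,
`medium`, `high`, with network-median grazing 0.1, 0.3, 0.5) are chosen
to put an isolated calibrated reef in each of those three regions.

### Calibration of the default rates

The literature anchors $a = 0.1$, and we take $r = 1$, $\gamma = 0.8$.
The remaining free scalar is the median coral mortality. The package
calibrates it with `calibrate_regimes()`: for a single reef with unit
self-retention, it scans mortality values and keeps those for which the
grazing medians 0.1/0.3/0.5 fall into the macroalgal / bistable / coral
regions respectively. The admissible band is roughly $d \in [0.40, 0.55]$
and the package default is $d_{med} = 0.44$:

```{r calibration}
calibrate_regimes(d_values = c(0.30, 0.38, 0.44, 0.50, 0.58))
```

## The synthetic seascape

The survey data behind analyses of this kind (per-reef benthic covers,
herbivore densities, sediment exposure, closure membership) are
typically sensitive and not redistributable, and hydrodynamic dispersal
simulations require ocean-current reanalysis products. The package
therefore ships a generator that reproduces the *statistical structure*
those inputs feed into the model, so every stage is testable
end-to-end:

* **Geometry** — `generate_seascape()` places reefs in clusters around
  fishing-ground centroids inside a roughly one-degree tropical bounding
  box (pairwise distances of 0–100 km, the scale at which the dispersal
  kernels act).
* **Closures** — a configurable fraction of reefs (default 21/75) each
  anchor their own periodic fishery closure; the closure-expansion
  intervention grows these points outward.
* **Covariates** — herbivore density is log-normal (median 100 kg/ha,
  log-sd 0.75, strongly right-skewed as fish survey biomass tends to
  be); the sediment index decays exponentially with distance from the
  simulated coast (the southern box edge) with multiplicative noise, so
  it is spatially autocorrelated; initial covers are Beta draws
  constrained to the simplex.
* **Dispersal** — `generate_connectivity()` evaluates an isotropic
  exponential kernel $p_0 e^{-\mathrm{dist}/\lambda}$ with range
  $\lambda$ = speed × pelagic larval duration (PLD), log-normal
  roughening (mean one, log-sd 0.5) and pruning of entries below
  $10^{-4}$. This stands in for a hydrodynamic simulation while keeping
  the analysis-relevant features: dispersal range grows with PLD, long
  links are sparse, and short-PLD graphs fragment into several weak
  components.

Two default kernels differ deliberately. Coral larvae drift for tens of
days and settle with low per-pair probability ($p_0 = 0.10$, PLDs
10–130 days pooled by `weighted_average_connectivity()`); macroalgal
gametes are viable for about five days and settle close to home
($p_0 = 0.8$, PLD 5). This asymmetry is what lets local bistability
survive inside the network: macroalgal propagule pressure is strong but
local, while coral recruitment is a thin, spatially heterogeneous
network subsidy. The kernel speed default (0.15 km/day) keeps the
longest kernels comparable to the seascape diameter rather than flat
across it; a flat kernel pools all larvae into one market and makes the
whole network flip as a unit, which is neither realistic nor
informative about spatial management.

These defaults were chosen once, for qualitative plausibility of the
regime structure (essentially no healthy reefs under low grazing, a
heterogeneous minority under medium and high), and are documented as
plumbing, not as estimates of any real seascape. What passing tests
show is that the *machinery* — regimes, interventions, metrics,
decision analysis — behaves correctly on data with this structure; they
do not validate predictions for any real reef system, whose covariate
marginals, kernels and parameter constructions would need to be fitted
from data.

## Parameterisation

`grazing_from_density()` multiplies herbivore density by a single
consumption-rate constant chosen so the network median equals the
scenario median exactly (even-length medians average the central pair).
The map is multiplicative: zero-density reefs stay at zero and ranking
is preserved. `mortality_from_sediment()` linearly rescales the
sediment index onto $[d_{med}(1-s),\, d_{med}(1+s)]$ (default spread
$s = 0.5$), pinning the median reef exactly at $d_{med}$; a constant
index degenerates cleanly to constant mortality.

## Management interventions

`intervention()` declares one manipulation; `default_interventions()`
returns the six conventional arms:

| arm | action |
|---|---|
| M1-2km | closures grow to a 2-km radius, same fishing ground only |
| M1-5km | closures grow to 5 km, across ground boundaries |
| M2-10%, M2-25% | coral mortality reduced by 10% / 25% on all reefs |
| M3-2km+10%, M3-2km+25% | both at once |

The radius is an exact haversine threshold (boundary ties included;
Earth radius 6371 km). A captured reef inherits the original closure
reef's grazing rate, or the equal-weight mean when several closures
capture it; the same averaging rule extends to an original closure reef
that falls inside another closure's radius. Closure expansion touches
only grazing and water quality only mortality, so the combined arm is
order-independent — asserted in the test suite, not assumed. The
"scattered" water-quality scope resolves the 2-km expansion set first
and reduces mortality only there, enabling a like-for-like comparison
between the two intervention families on exactly the same reefs.

## Metrics and the EVPI decision analysis

A reef is *healthy* when its final coral cover strictly exceeds 30%
(values within $10^{-9}$ of the threshold are not counted). Per-reef
intervention effects are reported as percentage-point differences
against the same-scenario baseline. `net_migration()` summarises the
coral matrix as immigration minus emigration per reef, self-retention
excluded.

`compute_evpi()` implements the expected value of perfect information
over the scenario axis: the mean over scenarios of the per-scenario
best count ("average of the best") minus the best scenario-averaged
count attainable by a single intervention ("best of the averages").
EVPI is non-negative by Jensen's inequality, invariant under adding a
constant to every cell, and scales linearly with the metric — all
property-tested. A zero EVPI means one intervention dominates under
every scenario, so resolving the grazing uncertainty would not change
the decision.

```{r evpi-example}
counts <- matrix(c(1, 11, 12,  1, 12, 12,  0, 12, 14,
                   1, 13, 16,  1, 12, 14,  1, 15, 16),
                 nrow = 6, byrow = TRUE,
                 dimnames = list(c("M1-2km", "M1-5km", "M2-10%", "M2-25%",
                                   "M3-2km+10%", "M3-2km+25%"),
                                 c("low", "medium", "high")))
compute_evpi(counts)
```

## Numerical choices

* **Integrator** — lsoda with `rtol = 1e-8`, `atol = 1e-10`; the suite
  cross-checks it against an independently written fixed-step RK4 at
  `dt = 0.01` to $10^{-4}$ max-abs. "20,000 time steps" is interpreted
  as integration to $t = 20000$ in model time with unit-spaced outputs
  (the equations are continuous; the phrase mirrors the `times` vector
  idiom of ODE solvers), and the residual $\max|dX/dt|$ at the endpoint
  is recorded so `check_equilibrium()` can verify the run settled.
* **The grazing singularity** — $g M/(M+F)$ is indeterminate at the
  all-coral corner. The denominator is floored at $10^{-12}$ and states
  are clipped onto the simplex inside the right-hand side; this is
  identical to the raw expression at every valid state but keeps the
  vector field continuous where trajectories graze the corner (a hard
  zero cutoff makes the stiff solver's step size collapse precisely in
  the strongest-intervention runs, e.g. mortality reduced to zero).
* **Round-off policy** — decaying covers can overshoot $[0, 1]$ by
  $\sim 10^{-9}$ at these tolerances; stored states within $10^{-8}$ of
  a bound are clipped back to it, larger excursions are left visible.
  Free space is always reported as $1 - M - C$, never floored, so
  conservation is exact.
* **Degenerate inputs** — all-zero herbivore densities are an error
  (no multiplicative scaling can set their median); constant sediment
  maps to constant $d_{med}$; a zero-radius expansion captures nothing;
  an empty scattered set leaves mortality untouched; regime probes that
  end with $|C - M| < 10^{-6}$ are labelled `degenerate` rather than
  forced into a side.

## Problem sizes

The defaults run the full study scale: 75 reefs, three scenarios ×
(baseline + six arms) = 21 integrations to $t = 20000$, which completes
in well under a minute on a single core. The unit-test suite uses
smaller seascapes (8–40 reefs) and shorter horizons for bookkeeping
checks, and reserves full-scale runs for the acceptance properties
(spillover, sweep monotonicity, bitwise determinism of the grid). The
RK4 cross-check integrates five seeded 5-reef systems to $t = 50$,
where the fixed-step oracle is affordable at `dt = 0.01`.

## Known limitations

* The generator's marginals are plausibility stand-ins, not estimates;
  nothing here should be read as a prediction for any real seascape.
* No stochastic forcing, bleaching or storm disturbance, and no
  herbivore population dynamics: grazing is a parameter, not a state.
* The exponential kernel is isotropic; real larval transport is
  advective and anisotropic, which can matter for source-sink
  structure.
* EVPI is computed over the discrete scenario axis only (and, in
  `sensitivity_grid()`, over grid cells); no continuous priors and no
  partial-information (EVPPI) analysis.
* The pooling of EVPI across sensitivity axes is reported in two
  variants (per-cell and pooled over all cells jointly), since there is
  no single canonical choice; neither is privileged.
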