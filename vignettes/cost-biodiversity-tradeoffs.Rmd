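---
title: "When do cost data and biodiversity data earn their keep? Methods behind minset"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{When do cost data and biodiversity data earn their keep? Methods behind minset}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Systematic conservation planning asks which planning units to protect so
that every focal species reaches a representation target at least cost --
the *minimum set problem*. Two data layers drive the answer: per-unit land
cost and per-species occupancy probability. Both are expensive to obtain,
and practitioners routinely omit one of them. `minset` provides the
machinery to quantify what each layer is worth: exact minimum-set selection
with and without cost in the objective, a cheapest-first baseline that uses
no biodiversity information, and efficiency metrics that compare the three
across targets, habitat-suitability thresholds, and controlled levels of
relative data variability.

## The selection model

A problem instance has units $i = 1,\dots,n$ with costs $c_i > 0$ and
occupancy probabilities $p_{si} \in [0,1]$ for species $s$. A unit is
*suitable* for species $s$ when $p_{si} \ge \tau$ (the occupancy threshold
$\tau \in \{0.25, 0.50, 0.75\}$ in the default scenario design; the comparison is
inclusive). Suitability is per species: a unit unsuitable for one species
still contributes to another's constraint. With binary decisions $x_i$ the
exact selection solves

$$\min \sum_i w_i x_i \quad \text{s.t.} \quad
  \sum_{i:\, p_{si} \ge \tau} p_{si}\, x_i \;\ge\; T \sum_{i:\, p_{si} \ge \tau} p_{si}
  \quad \forall s,$$

with $w_i = c_i$ (`min_cost`) or $w_i = 1$ (`min_area`, the
no-cost-data variant) and a common target fraction
$T \in \{0.05, \dots, 1.00\}$. The `crank` baseline instead buys units from
cheapest to most expensive (ties by unit id) until every constraint is
satisfied, touching biodiversity data only to detect satisfaction. No
boundary-length or compactness term is used anywhere.

Two design points deserve justification:

* **Target denominator.** We default to the *post-threshold* total (the sum
  over suitable units). Under a pre-threshold denominator, 100% targets are
  generically infeasible whenever any occupancy mass sits below the
  threshold, yet the scenario design sweeps targets all the way to 100%. The
  pre-threshold convention remains available
  (`denominator = "pre_threshold"`).
* **Empty suitable sets.** A species with no suitable unit makes the
  instance infeasible outright; "capture 50% of nothing" is reported as
  infeasibility, not trivially satisfied, and infeasibility is a recorded
  status in curves, never an exception that aborts a sweep.

### Solving and optimality

Instances are solved as integer linear programs by HiGHS
(branch-and-bound, reached through `scipy.optimize.milp`; the package
batches many instances per solver invocation). The default relative
optimality gap is 1%, and gap 0 is used whenever a run is compared against
the exhaustive-enumeration oracle (`brute_force_min_set()`, guarded to 20
units, ties broken by lexicographically smallest id tuple).

One numerical reality of desk-scale instances is worth stating openly. When
an additive offset flattens the cost layer (see below), low-target
instances approach pure set-covering with near-equal weights: the optimum
selects some $k$ near-interchangeable units and the LP relaxation's bound
sits roughly $1/k$ below the integer optimum. At a few hundred units and
$k \approx 20$ that intrinsic bound gap ($\sim$5%) exceeds 1%, so *proving*
1% optimality can take orders of magnitude longer than finding the optimal
solution (at tens of thousands of units, where $k$ is in the hundreds, the
effect vanishes). For large sweeps the solver therefore accepts an optional
per-instance `time_limit`; when it bites, the incumbent is returned with
its actually-achieved bound gap reported honestly (`solver_gap`, status
`feasible_suboptimal` when above the requested gap). Every solution's
feasibility is re-verified in R regardless of how the solver stopped.

## Aggregation

Fine cells (1 ha in the emulated study system) aggregate to planning units
(1 km^2) by summing cost and averaging occupancy over axis-aligned
$f \times f$ blocks anchored at the origin. Partial edge blocks are an
error rather than a smaller unit, because mixed unit areas would distort
the unit-count objective. Aggregation conserves total cost exactly and the
area-weighted mean of every occupancy layer, and composes:
two-stage aggregation equals one-stage aggregation by the product factor.

## Manipulating relative variability

The *relative CV* of a scenario is
$CV_{rel} = CV_{benefit} / CV_{cost}$, where $CV = SD/\mu$ uses the sample
SD ($n-1$; the ratio identity holds under either convention as long as one
is fixed) and $CV_{benefit}$ is the mean of per-species occupancy CVs.
Adding the offset

$$\Delta_{cost} = \frac{CV_{rel} \cdot SD_{cost}}{CV_{benefit}} - \mu_{cost}$$

to every unit cost changes the mean but not the SD, so the achieved ratio
equals the requested level to floating-point accuracy -- an identity the
tests assert at $10^{-9}$. Because the shift is additive it also preserves
the cost ordering of units, so cheapest-first selection is invariant to it.
Three further conventions: the benefit CV is computed over the species in
the active scenario (one guild, since prioritizations run per guild) and at
planning-unit resolution (the scale the optimizer sees); and each
scenario's "percentage of total cost" uses its own offset-adjusted layer,
keeping every scenario internally consistent. All three choices are
options, not hard-wired.

## Efficiency metrics

For each scenario and method we build a cost-benefit curve: solution cost
as a fraction of the scenario's total landscape cost, per target in
$\{0.05, \dots, 1.00\}$. Efficiency is the area under the achieved-target
versus cost-fraction path, anchored at the origin and extended flat from
the last feasible point to cost fraction 1, so the AUC lives in $[0,1]$: a
diagonal curve scores 0.5 and a curve reaching the full target at
negligible cost tends to 1. Infeasible targets are excluded from the
support. The transposed orientation (area under cost as a function of
target, lower is better) is available because figure conventions differ
between studies. The value of a data layer is the *fractional gain*
$(AUC_{with} - AUC_{without}) / AUC_{without}$ -- `min_cost` vs `min_area`
for cost data, `min_cost` vs `crank` for biodiversity data. When the value
of biodiversity data is examined target-by-target instead, we use the
absolute savings $\mathrm{cost
fraction}_{crank} - \mathrm{cost fraction}_{min\_cost}$, i.e. percentage
points of total landscape cost, the same units as the curves themselves.

## The synthetic landscape generator

The real layers this package emulates -- occupancy-model predictions for 10
forest-associated and 10 human-associated bird species and a cadastral
assessed-value layer for a 27,250 km^2 region -- are not publicly
depositable, so the generator reproduces their *statistical structure* and
every analysis runs on seeded synthetic landscapes:

* **Cost**: $\mathrm{scale} \cdot \exp(s Z)$ of a standardized Gaussian
  random field $Z$, with $s$ root-found so the sample CV matches the
  configured target (default 7.25). At the default 200$\times$200 grid this
  spans roughly 7 orders of magnitude, mirroring heavy-tailed assessed land
  values; the mean is scaled to \$78M per aggregated planning unit.
* **Occupancy**: inverse-logit of $\alpha + aZ + bW$ with a species-specific
  independent field $W$. Per species, $\alpha$ is root-found to match a CV
  target and $a$ to match a signed correlation with the raw cost layer.
  CV targets ladder across the configured range (default 0.407--1.415) and
  correlation targets ladder across guild mean $\pm 0.05$ (defaults +0.083
  for the human guild, $-0.066$ for forest), emulating across-species
  scatter. The logit-scale SD $b = 2$ makes every species span near-0 to
  near-1 occupancies, as fitted occupancy maps do -- so suitable habitat at
  the strictest 0.75 threshold is the norm. Occasionally a high-CV species
  in a replicate still lacks any suitable planning unit after aggregation;
  that scenario is then infeasible by definition, is recorded as such, and
  drops out of cross-scenario comparisons (which are made on common
  support).
* **Spatial structure**: both fields share a Gaussian smoothing length of
  10 fine cells (one planning-unit side). Spatial autocorrelation has no
  empirical anchor in the emulated system, so this is a realism choice, not
  a calibration; none of the prioritization machinery uses adjacency (no
  boundary-length term), and `smoothing_length = 0` is allowed.

Defaults (200$\times$200 fine cells, aggregation factor 10, hence 400
planning units) are chosen so statistics are stable while exact
optimization stays desk-scale. What the generator does *not* emulate:
parcel geometry (units are square), land-cover covariates behind occupancy,
detection error, and any spatial pattern beyond second-order smoothness.
Passing directional tests on these landscapes shows the *logic* of the
data-value comparisons is faithfully implemented, not that a particular
real region would show gains of any particular magnitude.

## What the tests establish

* exact contracts: the $\Delta_{cost}$ identity at $10^{-9}$; solver
  solutions equal to exhaustive enumeration at gap 0 on 50 seeded small
  instances, and within 1% at the default gap;
* properties: cheapest-first never beats the exact optimum; costs
  non-decreasing in target; species totals non-increasing in threshold;
  unit-count solutions invariant to additive cost shifts;
* directions, on 10 seeded default landscapes (the CV sweep at threshold
  0.75, matching the default scenario design; the threshold comparison on the raw cost
  layer): the gain from cost data declines as $CV_{rel}$ rises; the gain
  from biodiversity data rises with $CV_{rel}$; biodiversity data matter
  more at higher targets and stricter thresholds; and the
  positively-cost-correlated guild gains more from cost data than the
  forest guild. Exact-magnitude reproduction is out of scope by design: the
  original magnitudes derive from undeposited proprietary layers.
* calibration: each default landscape's cost CV within 15% of 7.25, species
  CVs inside a widened (0.3, 1.8) band, and guild-mean correlation signs
  (+ for human, $-$ for forest).

Sweep problem sizes in the tests (400 planning units, 10 species per guild,
10 replicate seeds, 0.5 s per-instance proof cap in the directional sweep)
are the package's chosen desk-scale study conditions; they keep a full run
in the tens of minutes on one CPU.

## Worked example

```{r example}
library(minset)

cfg <- landscape_config(seed = 1)
land <- generate_landscape(cfg)
units <- aggregate(land)

sp <- guild_species(units, "human")
units8 <- apply_relative_cv(units, 8, sp)

mc <- build_curve(units8, sp, occupancy_threshold = 0.75,
                  method = "min_cost", time_limit = 1)
ma <- build_curve(units8, sp, occupancy_threshold = 0.75,
                  method = "min_area", time_limit = 1)
cr <- build_curve(units8, sp, occupancy_threshold = 0.75, method = "crank")

fractional_gain(curve_auc(mc), curve_auc(ma))  # value of cost data
fractional_gain(curve_auc(mc), curve_auc(cr))  # value of biodiversity data
```

## Known limitations

* Exact solves need the HiGHS backend (`minset_solver_available()`); the
  enumeration oracle and the cheapest-first baseline run without it.
* Proving 1% optimality on offset-flattened cost layers is intrinsically
  slow at a few hundred units (see above); use `time_limit` and read
  `solver_gap`.
* The generator calibrates *sample* statistics per seed, so landscape-level
  quantities are exact by construction while unit-level quantities (e.g.
  benefit CV after aggregation) inherit modest aggregation shrinkage.
* Square grids only; irregular parcels and locked-in/locked-out units are
  out of scope, as are simulated-annealing solvers and compactness terms.
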