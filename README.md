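# minset

Systematic conservation planning buys a portfolio of planning units that
meets a representation target for every focal species at the least cost —
the *minimum set problem*. Both data layers behind that decision are costly
to obtain: spatial land value (cadastral assessments, opportunity costs)
and spatial biodiversity features (occupancy-probability maps). `minset`
is a toolkit for planners and ecological modellers who want to quantify
what each layer is worth before paying for it.

## What it computes

For planning units $i$ with costs $c_i$ and species occupancies
$p_{si}$, the exact prioritization solves the binary integer program

```
minimize    sum_i w_i x_i            w_i = c_i  (min_cost)  or  1  (min_area)
subject to  sum_{i : p_si >= tau} p_si x_i  >=  T * sum_{i : p_si >= tau} p_si   for every species s
```

over suitability thresholds `tau` (0.25/0.50/0.75), targets `T` (5–100% in
5% steps), for a forest-associated and a human-associated species guild —
solved by HiGHS branch and bound to a 1% optimality gap by default. A
cheapest-first baseline (**C-rank**: buy units from cheapest to most
expensive until all targets are met) represents planning with cost data
only. The package then:

* aggregates fine-resolution layers to planning units (cost summed,
  occupancy averaged);
* rescales the cost layer with an additive offset
  `delta = CV_rel * SD_cost / CV_benefit - mu_cost`, which pins the ratio of
  benefit CV to cost CV at chosen levels (2/4/8/16) without changing the
  cost SD;
* builds cost-benefit curves (solution cost as a share of total landscape
  cost per target), scores them by area under the curve, and reports
  fractional efficiency gains between data-inclusion scenarios;
* generates seeded synthetic landscapes calibrated to realistic structure:
  heavy-tailed costs (CV ≈ 7.25, many orders of magnitude), species
  occupancy CVs laddered over 0.407–1.415, and weak signed cost–occupancy
  correlations (positive for human-associated species, negative for
  forest), so every analysis is reproducible without proprietary data;
* includes an exhaustive-enumeration oracle for small instances, used to
  verify solver optimality independently.

## Worked example

```r
library(minset)

cfg   <- landscape_config(seed = 1)       # 200x200 fine cells -> 400 units
land  <- generate_landscape(cfg)
land
#> Synthetic fine landscape: 200 x 200 cells, 20 species (10 forest + 10 human)
#>   cost: mean 7.8e+05, CV 7.250, range 7.01 orders of magnitude
#>   occupancy CVs: 0.457 - 1.365

units  <- aggregate(land)
sp     <- guild_species(units, "human")
units8 <- apply_relative_cv(units, 8, sp)  # benefit CV = 8 x cost CV

mc <- build_curve(units8, sp, occupancy_threshold = 0.75,
                  method = "min_cost", time_limit = 1)
ma <- build_curve(units8, sp, occupancy_threshold = 0.75,
                  method = "min_area", time_limit = 1)
cr <- build_curve(units8, sp, occupancy_threshold = 0.75, method = "crank")

fractional_gain(curve_auc(mc), curve_auc(ma))   # value of cost data
#> [1] 0.0009
fractional_gain(curve_auc(mc), curve_auc(cr))   # value of biodiversity data
#> [1] 1.9696
```

Read: with biodiversity variability pinned at 8 times cost variability,
adding cost data to an already-biodiversity-informed plan buys almost
nothing (+0.1% efficiency), while adding biodiversity data to a cost-only
plan triples its efficiency (+197%). At low relative CV the picture
reverses in degree — exactly the trade-off the package is built to expose.
A single solve looks like:

```r
pr <- minset_problem(units8, sp, target_fraction = 0.5,
                     occupancy_threshold = 0.75)
prioritize(pr, "min_cost")
#> Minimum-set solution (min_cost): optimal_within_gap
#>   117 of 400 units selected; monetary cost 5.3589e+11; objective 5.3589e+11
#>   target 50%, threshold 75%; min representation 50.0%
```

`run_experiment(scenario_grid(...))` sweeps the full guild × threshold ×
relative-CV × method grid and writes tidy `results.csv` / `efficiency.csv`
/ `provenance.json`; `inst/cli/minset-cli.R` wraps the same functions for
shell use (`generate`, `aggregate`, `rescale`, `solve`, `curve`, `sweep`,
`report`).

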