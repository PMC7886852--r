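---
title: "Carrying-capacity assessment of coral reef islands: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Carrying-capacity assessment of coral reef islands: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corecc)
```

## The model

Coral reef islands are small social-ecological systems under pressure
from population growth, tourism and construction. The question carrying
capacity asks is whether the pressure human activities place on the
island stays within the support the system can provide. `corecc`
formalises this as a set of *paired* pressure-support indicators: each
indicator is a matched pair $(p, s)$ in identical units where the
support value $s$ is the threshold against which the pressure $p$ is
judged. Pairs are arranged in a three-level tree — four dimensions
(resource supply, environmental assimilation, ecosystem services,
socio-economic supporting), core factors within each dimension, and
indicators within each factor.

Each pair yields a **surplus ratio**

$$d = \frac{s - p}{s} = 1 - \frac{p}{s},$$

positive when the support exceeds the pressure (surplus), zero at full
load, negative under overload. Because $p \ge 0$ and $s > 0$, $d \le 1$
with no lower bound: an indicator loaded at 2.45 times its support
scores $-1.45$, and such values are legal and not clamped.

Sibling ratios combine upward by the vector-modulus (RMS) rule

$$D = 1 - \sqrt{\tfrac{1}{n}\sum_{j=1}^{n}(1 - d_j)^2},$$

applied identically at every level: indicators into a factor or
dimension, and the dimension ratios into the overall index. Each
child's *load factor* $1 - d_j$ enters quadratically, so one heavily
overloaded indicator drags its parent down more than an arithmetic mean
would — a deliberate precautionary property. The rule is permutation
invariant, reproduces a singleton or a set of equal children exactly,
never exceeds its best child, and is strictly increasing in every
child. These invariants are property-tested on thousands of random
trees against an independently coded re-evaluation.

Weights are equal by default at every level. A per-child weight hook
exists in the constructors and the configuration schema for localised
assessments, but nothing in the bundled case study uses it.

### Carrying states and the warning buffer

Ratios map to four states: `over-loaded` ($d < 0$), `full-loaded`
($d = 0$), `warning` ($0 < d < w$) and `surplus` ($d \ge w$), where
$w$ is the warning-buffer width (default $0.10$, configurable in
$[0, 1)$; $w = 0$ disables the buffer). The buffer exists because most
indicator values are estimates with appreciable uncertainty: a small
positive surplus is too close to the critical point to be called safe.
A ratio of exactly zero reports `full-loaded`, not `warning`.

### Aggregation modes

A dimension aggregates in one of two modes, set per dimension:

* **flat** — all indicators of all its factors are pooled into a single
  RMS aggregation; the factor grouping is descriptive.
* **nested** — each factor's indicators aggregate first, and the
  dimension then aggregates the factor ratios, so a factor with many
  indicators counts once rather than once per indicator.

The distinction matters. In the bundled Zhaoshu Island tree the
ecosystem-services dimension is nested (the terrestrial factor holds
one Sum-LAI indicator; the coral-reef factor pools four coral
indicators first) while the other three dimensions are flat. This
mixed convention is the one that reproduces the published dimension
results, and it is also the defensible choice on its merits: without
nesting, the four coral indicators would outvote the single terrestrial
indicator four to one.

## Support-end estimators

The tree can be filled from raw data with one estimator per core
factor.

**Suitable construction land.** A weighted multi-factor raster overlay:
per cell, $C = \sum_j W_j C_j$ over the factor grade layers (land
cover, fracture zone, mean gradient, soil property), except that any
factor grading a cell 0 vetoes it outright — a forbidden factor cannot
be compensated by good scores elsewhere. Grades default to the
$\{0, 1, 3, 5\}$ convention and weights must sum to 1 (checked to
$10^{-9}$). Scores classify into forbidden / limited / less-suitable /
suitable at thresholds $(t_1, t_2) = (2, 4)$ by default, and the
support value is the area of the top two classes. Layers are exchanged
as ESRI ASCII grids (`read_asc()` / `write_asc()`, round-trip exact).
The grade scale and thresholds are conventions, not published values,
and are configurable.

**Available water.** A sum over a *named, open* component list
(canonically ground water, transferred water, reclaimed wastewater,
desalinated water). Open because island water budgets differ; a surface
water component can simply be added. Units are a consistency tag, not
converted: whether a tonne equals a cubic metre is the user's call.

**Seawater assimilative capacity.** The total-maximum-load linear
program: given a response field $P_{ij}$ (concentration increment in
sea area $i$ per unit load from source $j$, precomputed by an external
hydrodynamic water-quality model), maximise total load
$\sum_j Q_j$ subject to $\sum_j P_{ij}Q_j \le C^s_i - b_i$ and
$Q^l \le Q \le Q^u$. The optional per-area background $b_i$ (default 0)
is there because practical load allocation needs it. The simplex method
(`boot::simplex`) solves the program after shifting to
$x = Q - Q^l \ge 0$; when several optimal allocations exist only the
total capacity is well-defined, and the reported load vector is the
vertex the solver returns. Tests verify the optimum against a
brute-force enumeration of all basic feasible solutions. Multiple
pollutants (inorganic nitrogen and phosphorus in the case study)
combine into the single water-assimilation indicator by the most
binding pollutant (minimum) by default, with the RMS rule as an
alternative.

**Terrestrial ecosystem services.** The Sum LAI: the mean leaf-area
index of the island's land-cover types weighted by area share, with a
reference LAI table (`default_lai_table()`: farmland 3.0, garden 3.0,
woodland 5.0, grassland 2.0, wetland 6.5, construction land 0.5, other
1.0 m²/m²), overridable in the configuration.

**Coral reef ecosystem services.** Point-intercept transects give
hard-coral coverage as $100\,n/M$ (the printed product form of this
formula in some sources cannot yield a percentage; the variable
definitions force the ratio). Belt transects give fish density as
$N/(2LW)$ — the strip is surveyed on both sides of the line, hence the
2. Species numbers pass through as raw counts. Per-transect estimates
pool by an effort-weighted mean (equal by default); the pooling rule is
package plumbing, since published assessments report one value per
indicator without stating one.

## The synthetic-data generator

`make_island()`, `simulate_point_intercept()`, `simulate_belt()` and
`make_response_field()` generate every input class with known ground
truth, so the whole chain is testable without field data. Defaults
emulate a small coral reef island of the study region: a 47 × 47 grid
of 10 m cells (≈ 0.22 km², the case-study island's area), the four
classic suitability factors with grades drawn from $\{1, 3, 5\}$ with
probabilities $(0.25, 0.45, 0.30)$ and a 10 % forbidden fraction, and a
woodland-dominated cover mix. Transect counts are binomial (point
intercept) and Poisson (belt) with the true coverage and density as
parameters; response fields decay with source-area distance and ship
with standards guaranteed feasible with slack. One root seed splits
into independent per-generator streams by hashing the generator label
(`sub_seed()`), so adding a generator never perturbs existing outputs.

What the generator does *not* emulate: spatial autocorrelation in the
rasters beyond independence, overdispersion or schooling in fish
counts, observer error in point-intercept records, and any real
hydrodynamics behind the response field. Passing tests therefore show
the estimators are correct under the stated sampling models, not that
those models fit any particular reef.

Simulation sizes in the test suite (1000 transects for the
recovery checks, 200 random programs for the LP oracle, 1000 random
ratio sets for the aggregation invariants, 8 × 8 rasters for the
overlay oracle) were chosen as the smallest sizes at which the
statistical checks have power; all are the package's own choices.

## The bundled case study

`zsi_tree()` returns the Zhaoshu Island (Xisha Islands) 2017 tree with
the published per-indicator surplus ratios: land 0.38, water 0.44,
water assimilation 0.87, Sum LAI −0.04, hard-coral coverage −1.45,
hard-coral species 0.14, fish density −0.67, fish species 0.14, GDP
per capita 0.04, environmental-protection investment 0.08, R&D
expenditures −0.60. Raw pressure/support values were mostly not
published, so each pair is materialised as $(p, s) = (1 - d, 1)$, which
reproduces every ratio exactly and keeps the full aggregation chain
runnable end to end.

```{r}
fit <- corecc(zsi_tree())
fit
```

Two quirks of the source table are handled deliberately. First, the
environmental-protection-investment row prints degree 5 alongside ratio
0.08; the degree consistent with the ratio is 8, and that is what the
package reports. Second, whether the published overall 5 % was computed
from rounded or unrounded dimension ratios is unstated; `corecc`
carries full precision throughout and rounds only for display, which
reproduces 5 % either way. The recomputed ecosystem-services overload
degree is 35 % against a published 36 % — attributable to the two-decimal
rounding of the published indicator ratios that are this fixture's
inputs.

## Numerical choices and degenerate inputs

* All stored values are full precision; `print`/`summary`/CSV round to
  two decimals (ratios) and whole percent (degrees), the JSON report
  keeps full precision.
* Weight sums are checked to $10^{-9}$; LP constraint satisfaction is
  verified to $10^{-9}$ relative; classification boundaries are closed
  on the suitable side ($d = w$ is `surplus`, score $= t_1$ is
  `less-suitable`).
* Empty aggregation sets, non-positive supports, negative pressures,
  mismatched raster shapes or no-data masks, infeasible lower load
  bounds and unknown configuration keys all fail fast with the
  offending node or key named; configuration validation reports *all*
  violations at once, not the first.

## Limitations

The assessment is a snapshot: no time series, no trend, no spatial map
of carrying capacity. Pressure-end targets (target Sum LAI, target
coverage, expected GDP, planned investment shares) are inputs the user
must supply from standards or plans — the package computes none of
them. Equal weighting is a statement of ignorance, not of importance;
for islands with different economic structures a localised weight set
may be more faithful, and the hook exists. And the RMS aggregation, by
construction, lets a large surplus in one dimension partially offset
overload in another at the overall level — which is why the per-
dimension states, not the single overall number, are the primary
reading of a report.
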