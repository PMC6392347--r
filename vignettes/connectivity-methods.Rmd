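---
title: "Modelling island connectivity under declining sea ice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling island connectivity under declining sea ice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icescape)
```

## The problem

Island-dwelling Arctic ungulates move seasonally between islands over sea
ice. Whether two islands are connected in a given season depends on the
ice between them; as ice declines, crossings become costlier and
eventually impossible, isolating populations. `icescape` models this as a
landscape-connectivity problem on a raster archipelago: every cell gets a
movement resistance, islands are core areas, and connectivity is
quantified three ways — circuit-theory current flow between all island
pairs, least-cost-path (LCP) networks, and current-flow centrality of the
islands in that network.

The package operates at a coarse analysis resolution (25-km cells by
default, the resolution of regional sea-ice model output). It does not
resample: all rasters entering a computation must already share shape,
cell size and origin, and any mismatch is an error.

## Resistance model

Resistance has two sources, mosaicked by the authoritative island-label
grid.

**Land.** Seasonal habitat probability-of-use in `[0, 1]` is reclassified
into ten bins per season (`spring_bin_table()`, `winter_bin_table()`).
The best bin gets resistance 1 and each successive bin one more, except
the two lowest-use bins (roughly 0–15 % probability) which jump to 20 and
30, so that animals route around effectively unused land and onto the
ice instead. Binning (rather than a continuous transform) deliberately
discards the precision lost when fine habitat models are aggregated to
the analysis grid. The printed bin edges touch; we resolve inclusivity as
half-open `[lower, upper)` intervals with the top bin closed, which makes
the assignment a total function on `[0, top]`. Probabilities above the
top edge are a validation error rather than silently clamped.

**Sea.** Sea-ice concentration (SIC, percent) maps to resistance as
`(100 - SIC) + offset` with `offset = 10`, and any cell below the
impassability cutoff (70 %) is impassable. Worked values: SIC 99 gives
resistance 11, SIC 70 gives 40, SIC 69.9 is impassable. The offset makes
every passable sea cell (resistance 10–40) costlier than any land cell
outside the two worst bins, encoding that ice crossings are harder than
land travel. The 70 % cutoff is generous for individual crossings but
appropriate for 25-km cells that can mix shore and open water. Both
parameters are tunable via `sic_transform_params()`.

Impassability is a genuine sentinel (`Inf`), not a large finite
resistance: impassable cells are excluded from the graph entirely, so no
current leaks through them.

## Seasonal aggregation

Two movement seasons matter: spring (April–June) and early winter
(November–December). Monthly SIC grids are averaged per season and year,
then annual means are averaged within decade groups (2021–2030 …
2091–2100). The historical reference period is one explicit 15-year
group (1991–2005). Means are unweighted; incomplete seasons or decades
are errors, never silently averaged over what is available, so scenario
comparisons always rest on the same number of grids.

## Circuit model

`build_graph()` turns a resistance surface into a conductance graph: one
node per passable cell, edges between orthogonal and (by default)
diagonal neighbours, edge resistance the arithmetic mean of the two cell
resistances, scaled by `sqrt(2)` on diagonals. This is the de facto
standard raster-to-network convention in circuit-theoretic connectivity
tools. The 8-neighbourhood is the default; 4 is available and handy for
hand-checkable examples.

For each unordered island pair, `solve_pair()` contracts the two focal
islands to zero-resistance supernodes (parallel edges merge by summing
conductances; all other islands keep their per-cell land resistances),
injects 1 A at one supernode, grounds the other, and solves the graph
Laplacian system by sparse Cholesky factorisation after eliminating the
ground row. Potentials give edge currents; a cell's current magnitude is
half the sum of absolute incident edge currents (each unit of
through-current counted once), and each focal island's full 1 A is
spread uniformly over its member cells for mapping. `effective
resistance` is the source potential. Pairs with no route are reported
unsolvable with zero current — losing a connection is a result, not an
error. `cumulative_current()` sums the per-cell magnitudes over all
unordered pairs (solving each pair once; with magnitude maps, direction
is irrelevant by reciprocity) and reports per-island means over all of
each island's land cells.

The test suite pins this solver to an independent dense
Laplacian-pseudoinverse implementation on randomized small grids (both
effective resistance and full current maps, 1e-8 relative), and checks
the classical invariants: series and parallel closed forms, reciprocity
under terminal swap, 1 A conservation, interior Kirchhoff residuals
below 1e-8 A, and Rayleigh monotonicity under randomized cell blocking.

## Corridor network

`cost_distance()` runs multi-source Dijkstra from all cells of an island
with step costs *identical* to the circuit edge resistances, so LCP and
circuit results live on the same weighted graph; that makes the
invariant "LCP cost >= effective resistance" exact, and the tests assert
it on every fixture. `least_cost_path()` returns the cheapest
island-to-island route. Tie-breaking is deterministic: the path is
traced by walking downhill on the cost-to-target field, choosing the
smallest `(row, col)` neighbour among cost-optimal steps, so reruns are
byte-identical. Islands that touch within one cell get an active
zero-cost link (they are closer than the analysis resolution). A link
whose path interior crosses a third island is kept but flagged
`pruned_intermediate` — the pair is not adjacent in the core-area sense —
and unreachable pairs are `severed`. `count_connections()` counts active
links only.

## Centrality

`network_current_flow_centrality()` works on the island-level graph, not
the raster: nodes are islands, and each active link conducts with
resistance equal to its cost-weighted distance. For every island pair in
a connected component a 1 A two-terminal solve is run; each terminal is
credited the full amp, other islands their through-current (half-sum of
absolute incident link currents), and links the absolute current they
carry. Raw centrality is the sum over pairs. This convention makes the
smallest cases exact: a single link gives both terminals 1; a three-node
path gives (2, 3, 2). On trees it coincides with path counting, which
the tests exploit as an oracle. `area_correct()` divides by island area
(km²) to highlight small but pivotal stepping-stone islands and
recomputes both rank orders.

Two numerical details: zero-cost links (touching islands) conduct at
`1 / 1e-9` rather than infinitely, keeping the island Laplacian finite —
the floor is far below any realistic cost-weighted distance, so it never
affects rankings; and in late, nearly disconnected decades absolute
centralities become very small, so rankings there should be read with
caution even though the package reports the values as computed.

## Synthetic archipelago and ice scenarios

No real rasters ship with the package; `generate_archipelago()` and
`generate_sic_series()` create inputs with the statistical structure the
analysis assumes, and `make_worked_fixture()` is a fixed 8×8
hand-assigned instance used by the oracle tests.

Islands are disjoint random disks (radius range in cells) with at least
one sea cell between any two, so labels are unambiguous core areas.
Habitat is smoothed Gaussian noise (box filter of configurable
half-width) plus a north-to-south increasing productivity trend,
rescaled on land to `[0, 0.83]` in spring and `[0, 0.88]` in winter —
the ceilings of the default bin tables — so generated surfaces always
lie inside the binning domain.

Monthly SIC follows
`clamp(baseline[month] - decline(year, month) - gradient * rows_south + noise, 0, 100)`
with `decline = rate * (year - start)`, multiplied by a winter factor in
November–December. Defaults, chosen once as a plausible caricature of
the real system: baseline 97/95/88 % (April–June) and 86/94 %
(November–December); decline rates 0, 0.45 and 0.9 % per year for the
historical, moderate and high scenarios (the high scenario loses ice
twice as fast); winter multiplier 1.5 (early-winter ice declines faster
than spring ice); latitude gradient 0.5 % per row so southern waters
open first; additive Gaussian noise with 2 % standard deviation,
clamped. One seed governs a generator call, and identical configurations
reproduce identical rasters.

What the generator does **not** emulate: real coastline geometry,
ice-dynamics physics (advection, ridging, interannual oscillations),
spatially correlated SIC noise, and the covariates behind real habitat
models. Passing tests therefore demonstrate that the machinery is
correct and that the qualitative scenario logic (south-first,
winter-first, monotone loss) follows from the stated generator — not
that any particular real archipelago behaves quantitatively this way.

## Pipeline

`run_pipeline()` composes the stages for every (season, scenario,
decade): decadal seasonal SIC → sea resistance → mosaic with binned
habitat → cumulative current → island network → area-corrected
centrality, returning tibbles (`summary`, `island_means`, `centrality`,
`links`) and optionally writing artifacts under
`<season>/<scenario>/<decade>/`. The mean cumulative current over all
land cells is compared against the baseline scenario's value for the
same season as `100 * (x - baseline) / baseline`; the baseline's change
against itself is 0 by construction. Runs are fully deterministic given
the configuration.

## Problem sizes

The examples and tests run at deliberately small scales: oracle
equivalence on random grids up to 8×8 (100 seeds), exhaustive-path LCP
checks on 6×6 grids, Rayleigh monotonicity over 200 randomized
perturbations, and an end-to-end declining-ice scenario on a 60×60 grid
with 8 islands across nine decades and two seasons. These sizes keep the
whole suite in the low tens of seconds while exercising every code path;
the implementation itself is sparse and scales to the few-thousand-cell
grids typical of coarse archipelago analyses.

## Known limitations

- One cell is entirely land or entirely sea; mixed coastal cells are
  resolved only through the lowered ice cutoff, as in the source
  transforms.
- No resampling or reprojection: inputs must arrive on the analysis grid.
- Corridors are reported as least-cost paths and costs, not as
  continuous corridor bands; pinch-point (bottleneck) mapping is out of
  scope.
- Absolute cumulative currents depend on the unordered-pairs convention
  (a factor of two against summing ordered pairs); patterns and rankings
  are unaffected.
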