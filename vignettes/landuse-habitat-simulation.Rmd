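---
title: "Coupled land-use simulation and habitat-quality assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled land-use simulation and habitat-quality assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`lusim` chains three models that are standard in landscape ecology — a
Markov chain for land-use *quantity*, a neural-network-driven cellular
automaton (CA) for land-use *location*, and a threat-decay habitat-quality
index for the *ecological consequence* — into one reproducible pipeline,
with a synthetic-landscape generator standing in for proprietary survey
rasters. This vignette documents the models, their assumptions, every
tunable that matters, and the design decisions taken where the underlying
methods literature is silent.

## The land system

Landscapes are categorical rasters over six land classes, in fixed code
order: cultivated land (1), woodland (2), grassland (3), waters (4),
construction land (5), unused land (6). Grids are row-major with the origin
at the top-left; every raster in an analysis must share shape and cell
size — mixed resolutions are rejected rather than resampled, which keeps
resampling semantics out of the core. Cells that are nodata in *any* layer
are excluded from sampling, allocation, and all area statistics. Raster
interchange uses the ESRI ASCII grid dialect (plain text; the format the
originating GIS workflows export); no GDAL binding is required anywhere.

## Demand: a Markov chain on class budgets

Cross-tabulating two epochs gives a 6×6 count matrix; row-normalising it
gives the transition matrix $P$ (rows = source class). Demand is projected
by iterating the one-step map $S_{t+1} = S_t P$; row-stochasticity
conserves the total exactly, and the projected vector is rounded to
integers by largest-remainder apportionment so it always sums to the
valid-cell count the allocator must hit. A class absent at the base epoch
receives an identity row. We iterate the *estimated decadal* matrix over
the planning steps directly rather than taking a matrix root for shorter
periods: that reproduces the standard workflow without spectral machinery,
and `period_years` is carried as metadata.

Scenarios are multiplicative edits to off-diagonal transfer probabilities
plus a binary conversion-cost matrix. The probability mass an edit removes
(or adds) is absorbed by the row's diagonal — restricted land *stays in
place*, which is the policy intent — with clipping and renormalisation
only in the pathological case of an increase driving the diagonal
negative. Three scenarios are built in: natural development (no edits),
cultivated-land protection (cultivated→construction ×0.6,
cultivated→woodland ×0.7), and ecological protection
(woodland/grassland→construction ×0.2, woodland/grassland→unused ×0,
waters→construction ×0.2, cultivated→woodland ×1.3,
cultivated→construction ×0.7), each with its own cost matrix.

## Location: the adaptive-inertia CA

Each cell's pull toward class $k$ is the product of four factors:

* **Suitability** $sp(p,k)$: a single-hidden-layer network (sigmoid hidden
  units, softmax output) trained on a stratified sample of the base map
  against nine driver layers (elevation, slope, GDP and population
  density, distances to towns, rivers, and three transport networks), all
  min–max normalised. The per-cell outputs are normalised to a probability
  simplex because the roulette draw below needs comparable class scores.
  Defaults: 12 hidden units (≈ driver count + class count), 3000 training
  cells, 300 full-batch Adam epochs, learning rate 0.05. Stratification is
  proportional with a 10-cell floor per present class; rare classes
  (waters, unused) are otherwise unlearnable on skewed landscapes. The
  network is implemented in the package (no neural-net dependency exists
  in the target environment) and is deterministic given its seed.
* **Neighbourhood effect** $\Omega_{p,k}$: the fraction of class-$k$ cells
  in the 3×3 Moore window (centre excluded — otherwise the conventional
  $N^2-1$ denominator could exceed 1), scaled by a per-class expansion
  weight (construction 1, unused 0.5, waters 0.4, grassland 0.3,
  cultivated 0.2, woodland 0.01). Border cells use their actual truncated
  neighbour count as denominator.
* **Adaptive inertia** $I_k$: starts at 1 and updates each iteration from
  the last two demand gaps $D^{t-1}, D^{t-2}$ (demand − current count):
  unchanged while $|D^{t-1}| \le |D^{t-2}|$; multiplied by
  $D^{t-2}/D^{t-1}$ for a worsening surplus; multiplied by
  $D^{t-1}/D^{t-2}$ for a worsening deficit. The printed form of this
  update in parts of the literature uses the same ratio in both non-trivial
  cases, which would *suppress* an under-allocated class and contradicts
  the mechanism's stated purpose; the package uses the canonical
  amplifying form and offers the literal one behind `strict_inertia`.
  Inertia is clipped to [0.1, 10] to prevent divergence on oscillating
  gaps.
* **Conversion cost**: the scenario's binary allowance; keeping the
  current class is always allowed.

Allocation visits all cells in a fresh seeded random order each iteration.
A cell whose class currently exceeds its demand may convert, by roulette
draw over the combined scores, to a class still below its demand; counts
update immediately, so no class overshoots and the total is conserved at
every step. A class whose count reaches demand is frozen — its cells lock
and it leaves every candidate set. Iteration stops when every class is
within `tol_frac` (default 0.2% of valid cells) of demand, or after
`max_iter` (default 300) sweeps; the per-iteration class counts are
returned for inspection and the result is flagged `converged` either way.
Two numerical choices matter here: a small floor (`omega_floor = 1e-4`) is
added to $\Omega$ inside the allocator only, so a growing class with no
neighbours anywhere on the map is not an absorbing state; and infeasible
demand (growth for a class no other class may convert to) is rejected
up-front with the class named. Roulette ties need no tie-break rule — the
draw itself resolves them.

Map agreement is scored cell-by-cell: overall accuracy (trace over total)
and Cohen's kappa with chance agreement $p_e = \sum_i r_i c_i / n^2$.

## Consequence: threat-decay habitat quality

Five threat sources degrade habitat: cultivated land (3 km reach, weight
0.7, linear decay), construction land (10 km, 1.0, exponential), and
national roads / provincial roads / railways (2 km, 0.8, linear). The two
land-class threats are derived from the map itself; the linear features
are supplied as masks. Impact at distance $d$ is $1 - d/d_{max}$ (linear)
or $e^{-2.99\,d/d_{max}}$ truncated at $d_{max}$ (exponential; the
constant puts the kernel at ≈0.05 at its reach, the convention of the
originating toolchain). Degradation weights impacts by normalised threat
weight and a class×threat sensitivity table; construction and unused land
are non-habitat (suitability and all sensitivities 0). Quality is
$Q = H\,[1 - D^2/(D^2+k^2)]$ with habitat suitability $H$ per class
(cultivated 0.6, woodland 1, grassland 1, waters 0.8) and half-saturation
$k = 0.5$ by default ($D = k$ halves quality; the default makes that test
crisp and is the toolchain's own). Threat intensity is binary presence;
the accessibility multiplier $\beta$ defaults to 1 everywhere (no layer
exists to inform it). Quality grades use fixed bins — poor [0, 0.4),
moderate [0.4, 0.6), good [0.6, 0.8), excellent [0.8, 1] — left-closed
with a closed top bin so every value maps to exactly one grade.

Because Eq.-style weight normalisation runs over the *active* threat set,
adding a whole new threat source rescales every weight share and can
locally raise quality; monotonicity ("more threat, less quality") holds
for a fixed threat set with growing footprints, and that is what the test
suite asserts.

## The synthetic world

The generator produces everything the pipeline consumes: smoothed
Gaussian-random-field terrain (correlation length `smoothness`, default 6
cells), slope as its gradient magnitude, GDP/population surfaces sharing a
seeded urban-core hotspot, towns sampled with probability ∝ GDP³, a
random-walk river, Bresenham-rasterised road networks that always span the
grid, and exact Euclidean distance layers (Felzenszwalb–Huttenlocher
transform) for all of them. Land use is the per-cell argmax of six affine
class scores on the normalised drivers plus smooth noise — construction
tracks the urban core, woodland steep high ground, waters valley floors
near the river — with intercepts calibrated by a Robbins–Monro iteration
so realised class fractions match the target prevalences. The default
world is 200×200 cells of 100 m (a 400 km² desk-scale domain; large
enough for stable class frequencies, small enough for seconds-scale
tests) with prevalences 40/22/27/2/6/3% mirroring a cultivated-dominated
agglomeration.

Epoch succession draws per-class change *quotas* from a known transition
matrix by largest-remainder apportionment and then chooses *which* cells
change with probability weighted toward cells adjacent to the destination
class. Placement is spatially coherent, but the marginal transition
frequencies match the matrix up to integer rounding by construction —
this is the module's core guarantee, and it is what makes
matrix-recovery tests sharp (total-variation error per row well below
0.05 at the default scale).

The default transition matrix was designed against the scenario cost
matrices, not estimated from anywhere: under each built-in scenario, a
class the cost matrix locks (cultivated under cultivated protection;
woodland under ecological protection) must have non-shrinking projected
demand, and every class's demanded net change must be routable from the
classes allowed to convert into it. Construction is the main growth
class, fed by cultivated land; woodland and waters budgets are
near-balanced, as in the kind of plains agglomeration the defaults
emulate. Violating this consistency does not crash the allocator — it
honestly reports non-convergence — but the shipped defaults converge
under all three scenarios.

What the generator does *not* emulate: real terrain statistics, realistic
road topology, census-anchored population surfaces, or any particular
region's class budget. A green test therefore establishes that the
*machinery* recovers designed-in structure, orders scenarios correctly,
and honours its conservation/cost/demand contracts — not that the package
reproduces any specific region's published map-level numbers, which would
require the original rasters.

## Reproducibility and scale

Every stochastic step takes an explicit integer seed (default 42) and
restores the RNG state afterwards; the C++ allocation sweep draws from R's
own RNG stream, so a pipeline run is bit-reproducible from its config, as
the manifest checksums verify. The test suite runs its heavier contracts
(demand attainment over 20 seeded runs, scenario ordering over 10 seeds)
on 100×100 worlds rather than the 200×200 default purely for runtime;
matrix recovery runs at the full default scale. On one CPU the entire
suite takes under a minute.

## Known limitations

Single-resolution grids only; no reprojection or vector I/O. The CA has no
patch-level mechanisms or planning-zone masks. The habitat model treats
threats independently (no synergy), with binary intensity and uniform
accessibility. GeoTIFF I/O is intentionally absent (no GDAL binding in the
supported environment); the ASCII dialect round-trips everything the
package produces.
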