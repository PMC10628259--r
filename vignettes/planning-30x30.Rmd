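---
title: "Methods: prioritizing and evaluating 30x30 expansion scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prioritizing and evaluating 30x30 expansion scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thirty30)
```

## The problem

Under the Kunming-Montreal Global Biodiversity Framework, nations have
committed to protecting 30% of their land by 2030. Where that 30% goes
determines how much biodiversity it captures. `thirty30` implements a
complete, testable planning-and-evaluation pipeline for exploring that
question: it builds climate-informed per-species feature layers, ranks land
with a greedy marginal-loss prioritizer in the core-area Zonation family
under a hierarchical protected-area mask, selects top-fraction scenarios
that vary *what* is prioritized (taxa, at-risk species, functional and
phylogenetic facets) and *how* protection is coordinated (whole-domain
versus independent subregional prioritizations), and scores every scenario
with a modified Species Protection Index (SPI) and weighted-endemism
capture.

Everything runs on synthetic landscapes from a seeded generator, so the full
pipeline is reproducible on a laptop with no geospatial downloads.

## Feature layers: climate "win-win" weighting

Each species enters the prioritizer as a single nonnegative raster. From a
current-climate suitability surface `cur` and a future-climate surface
`fut` (both in [0, 1]) we build

```
c = w_both * min(cur, fut) + w_now * cur + w_fut * fut
```

rescaled per species to a maximum of 1. With the enforced ordering
`w_both > w_now > w_fut > 0` (defaults 0.5, 0.35, 0.15), cells suitable in
*both* periods — candidate climate refugia, where presence is least
uncertain — score highest; cells suitable only today score mid; cells
suitable only in the future (the most uncertain) score lowest but remain
positive. The `min(cur, fut)` term is what makes overlap pay: at equal
underlying suitability the three cell types score in the stated order, which
is the substantive claim of refugia-weighted planning. The exact
coefficients are tunable (`winwin_coeffs` in `run_suite()`); only the
ordering is a contract. We apply the weighting additively on layers (rather
than multiplying species weights), which keeps the per-cell score a simple
linear functional of the two surfaces and makes the ordering contract
provable — a deliberate, documented design commitment where more than one
construction would satisfy the ordering.

Upstream of this, `ensemble_average()` (default weights 0.7/0.3) averages
two model projections per time slice, and the occurrence-side operators
(`grid_and_thin()`, `knn_outlier_filter()`, `buffer_range_truncate()`)
implement the standard cleaning steps for aggregated point archives:
half-open-interval gridding with one record per species per cell, single-pass
removal of points whose mean distance to their three nearest conspecific
records exceeds a per-group threshold (the mean of three, not one, catches
erroneous records logged repeatedly in nearly the same place), and zeroing of
suitability beyond a buffered range polygon. Per-group outlier thresholds
are deliberately required configuration: no defensible universal distance
exists, and the choice belongs to the analyst.

## Scenario weights

Thirteen default scenarios (`default_scenarios()`) differ only in species
weights and coordination scale:

* **National**: all species, kingdom-balanced — `kingdom_balance()`
  rescales weights so vertebrates, plants and butterflies each carry equal
  total weight, preventing the speciose kingdom from dominating.
* **Transnational**: weights equal each species' endemism share — the
  fraction of its continental range mass inside the planning region
  (`endemism_weight()`), so the nation concentrates on species it is
  globally responsible for.
* **Taxon scenarios** (birds, mammals, amphibians & reptiles, plants,
  butterflies): only that group's species, uniformly weighted.
* **At-risk scenarios**: species listed under the national scheme
  (special concern / threatened / endangered) or the global scheme
  (vulnerable / endangered / critically endangered), kingdom-rebalanced.
* **Facet scenarios**: weights are per-species functional or phylogenetic
  distinctiveness contributions, each normalized to sum to 1 within each
  kingdom. Phylogenetic distinctiveness is fair-proportion evolutionary
  distinctiveness (`fair_proportion_ed()`; scores provably sum to total tree
  length). Functional distinctiveness is a leave-one-out contribution to the
  area of the convex hull of species in the plane of the first two principal
  coordinates of a Gower trait distance matrix. The convex-hull area is a
  deterministic, exactly computable stand-in for a kernel hypervolume;
  interior species get zero (negative leave-one-out deltas are clipped
  before normalizing), which matches the "distinct species sit on the edge
  of trait space" intuition but ignores density structure inside the hull —
  a documented approximation.
* **Regional scenarios** (political subregions, ecological subregions):
  national weights, but prioritized independently within each subregion.

Facet weights *replace* the uniform base weights and are then
kingdom-balanced; multiplying them into the base weights would be an
equally defensible design, but replacement keeps the two facet scenarios
strictly comparable to the taxon scenarios.

## Prioritization: greedy marginal loss with a hierarchical mask

`coverage_to_class()` classifies cells: *excluded* (exclusion flag set, or
human-footprint index strictly above 10), else *protected* (fractional
protected-area coverage at least 0.43, inclusive), else *free*. The 0.43
coverage threshold is the calibration at which the count of protected cells
on a 1-km national grid matches the true protected-land share; both
thresholds are exposed as arguments.

`greedy_rank()` iteratively removes the remaining cell with the smallest
marginal loss. The default core-area rule is

```
delta_i = max_j  w_j * c_ij / Q_j
```

where `Q_j` is species `j`'s remaining total; an additive-benefit rule
(`sum_j`) is available. Zonation 5 ships a newer CAZ2 variant whose exact
formula is not published; we implement the classic core-area rule, name it
explicitly in the result metadata, and keep the rule pluggable rather than
guess at CAZ2's internals.

The hierarchical mask is implemented as removal phases: every free cell is
removed before any protected cell, so existing protected areas always
occupy the top ranks and new protection is chosen as a *complement* to
them. Ranks are removal-position over domain size, a permutation of
`{1/N, ..., 1}`.

Ties are broken by the lowest cell index (a seeded random tie-break mode
exists). The implementation caches marginal losses in a lazy min-heap —
valid because losses only grow as cells are removed — and re-evaluates every
candidate whose cached bound could tie the minimum, so its output is
*identical* to a naive full-recomputation pass; the test suite enforces this
equivalence on hundreds of random instances, ties included.

`subregion_rank()` runs the same algorithm independently inside each
subregion (remaining totals are recomputed within the subregion, so each
region prioritizes its own species and endemism), normalizes ranks within
subregions, and stitches them into one map. `top_fraction()` selects
`ceiling(f * N)` cells per ranking domain — the "at least f" reading of an
area target. On a whole-domain map a fraction below the protected share is
an error (protected land cannot be deselected); in a stitched map a
subregion holding more protected land than its quota simply contributes its
top quota (all of it protected) so that every subregion contributes exactly
its fraction.

## Evaluation

A species' range is the **sum of suitabilities** over the evaluation domain,
not a thresholded polygon. Targets follow the SPI construction: with
interpolated percentiles (type 7) of the range-size distribution, species at
or below the 10th percentile need 100% of their range protected, species at
or above the 90th need 10%, and in between the target is linear in
`log(range)` — "log-linear" pinned down as the only reading consistent with
the fixed endpoints (the standard SPI construction). A species is
*protected* when its selected range
fraction meets its target; SPI is the percentage of species protected.
Weighted endemism divides each species' suitability by its range total, so
each species contributes exactly one unit and the share of the surface
inside a selection is "percent of biodiversity captured". Trade-offs against
the reference scenario are `100 * n_alt / n_ref - 100`; facet trade-offs sum
the distinctiveness contributions of protected species as a share of the
facet total.

Two open choices are made explicit and configurable: evaluation uses the
current-climate stack by default (`evaluate_on = "winwin"` switches to the
combined layers), and percentile pivots are computed over the full evaluated
species pool, not per kingdom. All scenarios — including taxon scenarios
that prioritized only a subset — are evaluated against the full pool, which
is what makes their trade-offs comparable.

Scenario comparison: per-cell overlap classes across the 13 selections
(*All* = all scenarios, *Most* = at least `ceiling((n+1)/2)` — at least 7 of
13, *Some* = at least one, *No* = none), pairwise Pearson correlation of
rank maps over the common domain (rank values, not binary membership; binary
input works too), and non-metric multidimensional scaling of scenarios with
Bray-Curtis dissimilarity on the scenario-by-cell membership matrix — the
community-ecology convention for sites-by-species data, which is what
"scenarios as sites, cells as species" makes this. Zero dissimilarities
(duplicate scenarios) get a tiny seeded jitter so the embedding stays
defined.

## The synthetic generator: what it emulates, and what it does not

`generate_landscape()` produces every input on one grid, from one master
seed fanned out to fixed per-component child seeds (so components are
independently reproducible and the whole bundle is bit-identical under the
same config).

* **Suitability** — isotropic Gaussian bumps around per-species centroids;
  widths derive from a lognormal range-area law (`meanlog 5`, `sdlog 1` on
  a 100x100 grid), giving spatial autocorrelation and right-skewed range
  sizes by construction. Values below 0.02 are floored to zero, which keeps
  stacks sparse and gives occurrence sampling a support floor. The true
  range-size law of the real species pool is not documented; lognormal is a
  standard stand-in, flagged as such.
* **Gradient** — centroid latitude has density proportional to
  `exp(-g * northness)` with `g = 6` by default, putting roughly 78% of
  species centroids in the southern quartile and ~2% in the northern one.
  This is the "strong southern-border biodiversity gradient" that the
  coordination question is *about*: with a weaker gradient (`g` of 3 or
  less) regional and national coordination become nearly equivalent because
  enough species live everywhere, and the regional trade-off result should
  not be expected to reproduce.
* **Climate change** — future centroids shift 10 rows poleward (optionally
  contracting widths), producing the partial current/future overlap that
  win-win weighting needs.
* **Protected areas** — a clustered coverage field is rescaled so that the
  share of cells at or above 0.43 coverage equals `protected_fraction`
  (0.15, a realistic pre-protection level for a large high-latitude
  nation). Patches are many and
  small (about 25 cells each) and their centers lean away from the southern
  richness edge (`protected_bias = 1`), emulating a real network: parks sit
  disproportionately on low-productivity land, *but no subregion exceeds
  the 30% target* — an important structural property, since a subregion
  already past the target would invert the coordination comparison.
* **Availability** — a human-footprint surface scaled so ~5% of cells
  exceed the exclusion threshold of 10, concentrated in the south (where
  people are), plus a 5% clustered exclusion layer (unavailable land of
  other kinds).
* **Subregions** — political units are a Voronoi partition of random seeds
  (compact, irregular); ecological units are latitude-dominated bands,
  contrasting a political with a broadly climatic regionalization.
* **Species metadata** — at-risk status probability rises with rarity
  (~20% listed nationally, ~10% globally); traits are complete (imputation
  is out of scope); the phylogeny is a per-kingdom coalescent grafted into
  one rooted binary tree, so kingdoms are monophyletic; endemism shares
  compare within-grid bump mass to the bump's untruncated continental mass,
  so southern-edge species (ranges spilling over the "border") get low
  shares.
* **Occurrences** — `generate_occurrences()` samples points per cell with
  probability proportional to `suitability * exp(bias * southness)`,
  emulating the southern observation bias of aggregated archives, with an
  optional fraction of uniformly placed erroneous records for exercising
  the outlier filter.

What the generator does **not** emulate: real geography and climate
variables, dispersal limits, spatially structured trait evolution,
non-Gaussian range shapes (rivers, coasts), or correlated protected-area
siting with respect to species. Tests passing on these landscapes
demonstrate the pipeline's *algorithmic* correctness and the *direction* of
coordination trade-offs under a strong gradient — not numeric agreement
with any real nation's figures, which depend on continental data the
package deliberately does not require.

## Numerical choices and degenerate inputs

* Percentiles: type-7 (linear interpolation) everywhere, pinned for
  exactness.
* Tie-breaks: lowest flattened cell index, so rankings are reproducible and
  oracle-testable; a seeded random mode exists for sensitivity checks.
* Remaining totals `Q_j` are updated by subtraction; species with `Q_j = 0`
  contribute nothing to marginal losses.
* Selection quotas use `ceiling(f * N - 1e-9)`: the epsilon absorbs float
  noise when `f * N` is mathematically an integer.
* All-zero feature stacks rank purely by tie-break, with a warning.
* Species with zero range in the evaluation domain are dropped from the SPI
  denominator with a warning (they are unscorable, not unprotected).
* Degenerate percentile pivots (all ranges equal) send mid-species to the
  floor target, with a warning.
* Constant trait columns are dropped; an all-constant trait table is an
  error; a zero-area trait hull falls back to equal contributions.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline at the
default study size (100x100 cells, 300 species, 13 scenarios — a single
suite takes under a minute) and the prioritizer-oracle equivalence checks at
up to 100 cells and 10 species per instance, where the naive reference
recomputation is exact and fast. These sizes were chosen so the entire
evidence base regenerates from scratch in minutes while preserving the
structural features (gradient, hierarchy, subregions) the conclusions rest
on; the algorithms themselves have no size-specific logic.

## Known limitations

* The core-area rule here is classic CAZ, not a verified reimplementation
  of Zonation 5's CAZ2; rankings may differ from Zonation output on the
  same inputs.
* The functional hypervolume is a 2-D convex hull, not a kernel density
  estimate; contributions of interior species are zero by construction.
* SPI here is the modified, suitability-sum variant; it is not comparable
  to SPI values computed from binary range maps.
* Raster I/O is plain-text (ASCII grid / CSV); there is no GeoTIFF support,
  and real-data users must convert their rasters to matrices on the way in.
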