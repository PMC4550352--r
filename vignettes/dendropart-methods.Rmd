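---
title: "Methods: eigenfunction-based variation partitioning on dendritic stream networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eigenfunction-based variation partitioning on dendritic stream networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendropart)
```

## The question the package addresses

In glacierized catchments, meltwater imposes harsh conditions — near-zero
water temperature, low conductivity, high turbidity, unstable channels — that
fade downstream as groundwater dilutes the glacial signal. Benthic
macroinvertebrate communities along such networks may be structured by
*species sorting* (local conditions filter who persists), by *dispersal*
(overland flight, along-channel movement, downstream drift), or by glacial
water acting as a *dispersal barrier* for exclusively aquatic taxa.
`dendropart` implements the full analysis chain needed to weigh these
mechanisms against each other on a dendritic stream network: network-aware
distance matrices, a glaciality index, spatial eigenfunctions (MEM and AEM),
and adjusted-R² variation partitioning of Hellinger-transformed communities,
together with a seeded synthetic-data generator so that every stage is
testable without field data.

## Data model

A `stream_network` is a rooted tree (or forest): nodes carry planar
coordinates (projected metres — the package deliberately does no geodesic
math, appropriate for catchments a few kilometres across), elevations, and a
site flag; segments point downstream and carry lengths. Sites are classed
`first_order` (Strahler order 1 on the segment tree, overridable per site) or
`mainstem`. Distance matrices are always symmetric with zero diagonal, and
the package asserts this on every construction.

Five distance types are computed:

* **overland geographic** — straight-line Euclidean distance;
* **watercourse geographic** — summed segment lengths along the unique tree
  path (≥ the overland distance on any planar network);
* **overland altitudinal** — relief (max − min elevation) along the straight
  line, sampled from a DEM by bilinear interpolation at a configurable step
  (default: the raster cell size, which matches the DEM information content
  without aliasing);
* **watercourse altitudinal** — relief over the node elevations of the tree
  path; the channel is defined by its nodes, so the profile is the channel
  polyline rather than a raster resampling;
* **watercourse glaciality** — max − min glaciality along the path, over the
  path's segment values *and* the two endpoint site values (including the
  endpoints guarantees `d_ii = 0` and `d_ij ≥ |g_i − g_j|`).

Overland *glaciality* distances are never constructed: there is no difference
in glacial influence through the air, and the pipeline guards this by type.

## The glaciality index

Four harshness variables — temperature, conductivity, 1/turbidity,
1/Pfankuch (bottom score; higher Pfankuch = less stable channel) — are
min-max scaled to [0, 1] and ordinated by *non-centred* PCA (SVD without
column centring). Because all four scaled variables are simultaneously low at
glacial sites, the first axis tracks overall harshness. Two conventions make
the index deterministic where the ordination leaves freedom:

* **orientation** — the axis is flipped, if necessary, so that scores
  *anti-*correlate with the row means of the scaled matrix; glacial sites
  (uniformly low values) then receive the highest scores;
* **positivity** — scores are shifted by their minimum, so the least glacial
  site scores exactly 0.

Scores are kept on the singular-value scale (`U·S`). Any monotone affine
alternative would change only the absolute magnitude of glaciality distances,
not ranks, selections or partitions; min-max scaling additionally makes the
index exactly invariant to unit changes of the raw variables (multiplicative
for turbidity and Pfankuch, which enter as reciprocals; fully affine for
temperature and conductivity).

The index is computed over *all* sites, glacial and non-glacial alike, so
non-glacial streams receive a quantified (low) harshness score. Segments then
inherit the index of the nearest site upstream on their own branch; segments
immediately downstream of a tributary junction, which have no single upstream
site, inherit the nearest downstream site instead. Two sites on one segment
are not supported — split the segment. Attribution is idempotent and covers
every segment or fails loudly.

## Spatial eigenfunctions

**MEM (distance-based, the PCNM construction).** Distances above a truncation
threshold *t* are replaced by 4*t*; the matrix −d²/2 is Gower double-centred
and eigendecomposed. The default *t* is the largest edge of the minimum
spanning tree — the smallest threshold that keeps the network connected
(a disconnected threshold raises an error instructing a larger one).
Eigenvectors with eigenvalues above 1e−10 × the leading eigenvalue are
retained: these model positive spatial autocorrelation at scales from the
whole network down to neighbour pairs. On a regular transect the axes are
sinusoids of increasing frequency; the leading axis is a half-wave (one
interior sign change), not a monotone trend.

**AEM (directional).** Downstream processes are modelled from a site × edge
incidence matrix: a virtual origin is connected above every source, and
`E[i, k] = 1` exactly when edge *k* lies on the flow path from the origin to
site *i*. Columns are weighted by `w = 1 − (d/d_max)^α` (α = 1 by default),
so a long, steep or glacially harsh edge acts as a *partial* barrier; the
largest-distance edge receives a 1e−6 floor rather than a cut. The weighted,
column-centred incidence is decomposed by SVD; left singular vectors are the
directional eigenfunctions.

Because AEM singular values are always nonnegative, the positive/negative
split uses Moran's I instead: each axis is classified against the symmetrized
*immediate* downstream-neighbour relation (site pairs with no third site
between them on the flow path), retaining axes with I above the null
expectation −1/(n−1). The immediate relation is used deliberately: the full
transitive closure of downstream reachability is a complete graph on any
chain, which forces I = −1/(n−1) for every vector and carries no
autocorrelation signal at all.

## Canonical statistics

Community matrices are Hellinger-transformed (square root of relative
abundances; unit-sum-of-squares rows) before any ordination. RDA is plain
multivariate least squares of the centred response on standardized
predictors; collinear predictor columns are dropped by pivoted QR (tolerance
1e−8) with a warning, and the adjusted R² uses Ezekiel's formula with *m* =
the post-pruning rank. Fractions in variation partitioning are differences of
these adjusted R² values over subset unions of 2–4 predictor blocks,
recovered by Möbius inversion, so all exclusive fractions plus the residual
sum to 1 exactly and each unique fraction equals the direct difference
`adjR²(all) − adjR²(all minus block)` by construction. Negative fractions are
reported as-is and flagged "empty" — they mean a block explains less than
expected by chance. Note that exactly orthogonal blocks still show a nonzero
(negative) shared fraction on the adjusted scale; this is a property of the
Ezekiel correction, not an implementation artefact, and the unadjusted R²
remains exactly additive in that case.

Significance uses a pseudo-F permutation test:
`F = (SS_exp/m)/(SS_res/(n − m − q − 1))`. Without covariables the raw
response rows are permuted; with a conditioning block the *reduced-model
residuals* are permuted (Freedman–Lane), the accepted default for partial
canonical tests. `p = (1 + #(F* ≥ F))/(1 + n_perm)` with 999 permutations by
default. On samples so small that `n! ≤ n_perm` the permutation set is
enumerated exactly instead, with a warning.

Forward selection applies the double stopping criterion: a global test with
all candidates must pass first (on over-wide candidate sets the global fit is
rank-truncated rather than refused); then candidates are added greedily by
added R², stopping when a candidate's permutation p exceeds α *or* the
cumulative adjusted R² would exceed the global model's. Each step's test is
seeded from the master seed with the step index mixed in, making selections
exactly reproducible. The permutation scheme and count inside forward
selection are configurable; defaults match the main tests (199–999
permutations, residual permutation under the accumulated selection).

## The three models and the confounding report

For each of four taxon matrices (*all*, *flying*, *non-flying*,
*first-order sites*):

* **Model 1** partitions the community over the three environmental
  components *Glacier* (temperature, conductivity, 1/turbidity, 1/Pfankuch),
  *Instream* (width, depth, slope, pH) and *Resources* (epilithic algae,
  benthic organic matter), each min-max scaled.
* **Model 2** builds overland-MEM, watercourse-MEM and downstream-AEM
  variables from one distance family (geographic or altitudinal), gatekeeps
  each through the global test and forward selection, and partitions the
  survivors together with *Glacier* (up to four blocks). A variable whose
  global test fails is recorded as "no spatial structure" and excluded —
  forcing all its eigenvectors in would just launder noise into the
  partition.
* **Model 3** repeats the watercourse/downstream construction with
  *glaciality* distances (two blocks), asking whether differences in glacial
  influence along the channel act as dispersal barriers.

The confounding report then partitions, per spatial variable, across the
distance families' *selected* eigenfunctions and classifies each family as
`unique_significant`, `confounded_significant` (its own global test passed
but its unique fraction does not survive the other families), or
`not_significant`. Significance stars follow the usual convention
(`**` p < 0.01, `*` p < 0.05). First-order analyses rebuild eigenfunctions on
the site subset (MEM from the sub-matrix; AEM from the subset rows of the
incidence, dropping edges that no longer carry a retained site).

## The synthetic generator

`simulation_scenario()` fixes the study conditions; its defaults describe the
kind of catchment the package targets: 51 sites (25 on first-order channels)
on a bifurcating network with 8 headwaters of which the 4 highest are
glacial, elevations spanning 3886–4835 m, 85 taxa of which 70 fly as adults.
Latent glaciality `g` starts at 1 at glacial sources, decays exponentially
along the channel (0.15 per km — a scale at which glacial influence remains
detectable over ~15 km), and is diluted at confluences by flow-weighted
averaging with flow proportional to upstream headwater count. The four
harshness variables are monotone functions of `g` with multiplicative
lognormal noise (σ ≈ 0.08–0.12, enough noise to be realistic while keeping
the index recoverable); Instream and Resources variables are independent of
`g`.

Communities are Poisson (default; negative-binomial optional for
overdispersion) draws around
`log λ = intercept + env_effect·(niche − ½) + spatial term − barrier`,
with Gaussian niches along `g` (optima uniform on [0, 1], so the pool spans
glacial and groundwater specialists; breadth 0.3), a taxon-specific linear
combination of supplied eigenfunctions as the spatial term, and, for
non-flying taxa, a fixed log-scale penalty at every site whose channel path
from the taxon's source site crosses a segment with latent glaciality above
0.5. Effect-size defaults (env 1.5, spatial 0.6, barrier 1.2 on the log
scale) were chosen so that a default model-1 run explains well under half of
the community variation. The eigenfunction models explain more than that:
with Poisson observation noise the deterministic part of the log-mean
surface dominates, and forward selection adapts a flexible spatial basis to
it — real, overdispersed field counts leave far larger residuals, which is
one reason the negative-binomial observation option exists. The generator emits
its latent decomposition (`truth`) alongside the data so recovery tests can
compare estimated fractions against the generating structure.

What the generator does *not* emulate: temporal dynamics, overdispersion
beyond the negative binomial, taxon interactions, imperfect detection, and
spatially structured Instream/Resources variables. Passing recovery tests
therefore shows the machinery identifies the mechanisms it models, not that
real data are this clean.

## Numerical choices and test scales

Rank decisions use 1e−10 × the leading eigenvalue (eigenfunctions) and a
1e−8 pivoted-QR tolerance (predictors). Disconnected site pairs yield missing
distances that the eigenfunction builders reject. Degenerate glaciality
(constant across the network) is an error rather than a silent zero matrix.
When a predictor union approaches saturation (possible in the confounding
step when several families select many axes), fits are rank-truncated to
keep one residual degree of freedom; the resulting adjusted fractions are
extreme but well defined, and the bookkeeping identities still hold exactly.

The test suite exercises the statistical properties at deliberate scales:
type-I calibration with 1000 null datasets at 199 permutations; the forward
selection null with 500 simulations and 20 candidates; the three recovery
scenarios (sorting-only, AEM-driven, barrier) with 100 replicates each; and
full-pipeline determinism at 999 permutations, run twice and compared
byte-for-byte. Recovery scenarios switch off the mechanisms they are not
probing (e.g. the barrier scenario sets env and generic spatial effects to
zero) so each criterion isolates one generating mechanism.

## Known limitations

* The MEM/AEM settings (truncation at the largest MST edge, linear edge
  weighting with α = 1, the binary immediate-neighbour Moran weights) are
  canonical defaults, all configurable; other constructions are defensible.
* Forward selection re-tests selected axes in the final partition, which is
  mildly anticonservative — a known property of the standard workflow, shared
  by the procedure the package reproduces. The recovery criteria compare
  rates between matched splits, which cancels this bias.
* Adjusted-R² fractions from small site subsets (n = 25 first-order sites)
  with many candidate axes are noisy; the rank guard keeps them defined but
  they should be read qualitatively.
* No geodesic coordinates, no flow-accumulation hydrology, no shapefile I/O:
  networks are inputs, not derived from the DEM.
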