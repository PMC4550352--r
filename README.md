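# dendropart

Metacommunity variation partitioning on dendritic stream networks.

## What problem this solves

In glacierized catchments, benthic macroinvertebrate communities are shaped
by two kinds of processes that are hard to tell apart: **species sorting**
along the harsh environmental gradient that glacial meltwater imposes
(near-zero temperature, low conductivity, high turbidity, unstable channel
beds), and **dispersal** through space — overland flight, movement along the
channel, and downstream drift — which glacial water itself may block for
exclusively aquatic taxa. `dendropart` is for freshwater ecologists who want
to quantify the relative weight of these mechanisms from site-by-taxon
abundance data collected on a branching (dendritic) stream network.

The core statistic is **variation partitioning by partial redundancy
analysis**: for predictor blocks `X_1, …, X_k` (k ≤ 4) the community matrix
`Y` (Hellinger-transformed, `y'_ij = √(y_ij / y_i·)`) is decomposed into
unique, shared and residual fractions of adjusted R²,

    R²_adj = 1 − (1 − R²)(n − 1)/(n − m − 1)     (Ezekiel),
    unique(X_a) = R²_adj(all blocks) − R²_adj(all blocks except X_a),

with every exclusive fraction recovered by Möbius inversion so that they sum
to `R²_adj(all)` exactly, and unique fractions tested by seeded
permutation tests (pseudo-F, reduced-model residual permutation under
conditioning). Spatial predictors are **Moran's eigenvector maps** (MEM /
PCNM, from overland or watercourse distance matrices) and **asymmetric
eigenvector maps** (AEM, from the flow-directed network), pruned by a global
test plus forward selection with the double stopping criterion. A
**glaciality index** — non-centred PCA of min-max-scaled temperature,
conductivity, 1/turbidity and 1/Pfankuch — quantifies glacial influence per
site, is propagated to stream segments, and yields along-channel glaciality
distances that let glacial water be treated as a dispersal barrier.

Because such field data are rarely public, the package ships a seeded
generator for the whole study: a bifurcating network with glacial headwaters,
a downstream-decaying glaciality gradient, and communities with controllable
sorting, spatial and barrier structure.

## Worked example

```r
library(dendropart)

sim <- generate_dataset(simulation_scenario(), seed = 42)
sim
#> Synthetic glacial-catchment dataset
#> Stream network: 58 nodes (51 sites), 57 segments, 1 component(s)
#>   site classes: 25 first-order, 26 mainstem
#>   elevation range: 3886 - 4835 m
#>   community: 51 sites x 85 taxa (70 flying), poisson counts

# Model 1: glacial influence vs other environmental components
m1 <- run_model1(sim, n_perm = 999, seed = 42)
m1$splits$all$varpart
#> Variation partitioning (3 blocks, n = 51)
#>   unique [Glacier]    44.9% **
#>   unique [Instream]    -2.5%  (empty)
#>   unique [Resources]     0.1%
#>   shared (all overlaps)    2.0%
#>   residual                55.6%

# Model 3: do glaciality differences along the channel block dispersal?
m3 <- run_model3(sim, n_perm = 999, seed = 42)
m3$splits$nonflying$varpart
#> Variation partitioning (2 blocks, n = 51)
#>   unique [watercourse]     2.7% **
#>   unique [downstream]    32.2% **
#>   shared (all overlaps)   31.3%
#>   residual                33.8%
```

Reading the output: in this simulated catchment the *Glacier* component
uniquely explains 44.9% of community variation (`**` = permutation p < 0.01
with 999 permutations) while in-stream habitat and food resources explain
essentially nothing on their own — species sorting along the glacial gradient
dominates. For the exclusively aquatic (non-flying) taxa in model 3, the
directional downstream variable built from glaciality distances keeps a
large, significant unique fraction (32.2%) after accounting for the
symmetric watercourse variable: differences in glacial influence along the
channel act as a dispersal barrier, which is exactly the structure this
scenario generates. `run_full_analysis()` runs models 1–3 for all four taxon
matrices (all / flying / non-flying / first-order) plus the distance-type
confounding report; `fraction_table()` returns any model's fractions as a
data frame.

Lower-level entry points: `build_network()`, `overland_distance_matrix()`,
`watercourse_distance_matrix()`, `watercourse_altitudinal_matrix()`,
`overland_altitudinal_matrix()` (DEM line relief), `glaciality_index()`,
`assign_segment_glaciality()`, `glaciality_distance_matrix()`,
`mem_eigenfunctions()`, `aem_eigenfunctions()`, `hellinger()`, `rda_fit()`,
`permutation_test()`, `forward_select()`, `variation_partition()`,
`jackknife1_richness()`. A thin command-line wrapper lives at
`inst/scripts/dendropart.R`
(`simulate | index | distances | eigen | partition | report`).

See `vignettes/dendropart-methods.Rmd` for the model, conventions and
numerical choices.

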