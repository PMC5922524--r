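---
title: "Methods: quantitative bioregionalization and driver inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative bioregionalization and driver inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The analysis in one paragraph

`phytoregion` delimits floristic sub-regions from a site-by-species
presence/absence table and then asks which environmental factors explain
them. Pairwise compositional turnover among sites is measured with the
Simpson dissimilarity (beta-sim), embedded in three dimensions by
non-metric multidimensional scaling (NMDS), and interpolated onto a
regular grid by inverse-distance weighting, giving a spatially continuous
picture of compositional variation. The number of sub-regions is
estimated from Cailliez-corrected principal coordinates of the same
dissimilarity matrix, by running the L-method knee search on
within-group-sum-of-squares curves over every admissible maximum cluster
number and taking the modal optimum. K-means partitioning of the three
interpolated axes at that modal k yields the sub-region map. Site-level
environmental predictors (Koeppen aridity, glacial-interglacial change
measures, soil, topography, human footprint) and spatial eigenvectors
(Moran's Eigenvector Maps, MEMs) then enter multinomial logistic models
of sub-region membership, ranked by AICc, with the winning model's
deviance partitioned into unique environmental, unique spatial and
shared components. Two-way PERMANOVA compares the resulting
classification with alternative schemes.

# The pieces, their assumptions and their defaults

## Simpson turnover

For two sites with `a` shared species and `b`, `c` exclusive ones,
`beta_sim = min(b, c) / (min(b, c) + a)` (the Lennon et al. form). It is
zero whenever one flora nests inside the other, which makes it
insensitive to the large richness differences typical of compiled
floristic datasets — the reason it is the standard choice for
regionalization. Two non-empty sites sharing no species score 1
regardless of their sizes; sites with no species are rejected, so the
locality filter (`filter_localities()`, default minimum richness 5) must
run first. The filter mirrors the common compilation rule that localities
with fewer than five recorded species are too under-sampled to use.

## Ordination

`nmds()` wraps `vegan::metaMDS` (global NMDS, Kruskal stress-1, monotone
regression) with a mandatory seed, 20 random restarts by default, and a
deterministic sign convention (the site with the largest absolute score
is positive on each axis). Stress is reported as a fraction; the common
"stress = 17.3" convention is this value times 100. The Shepard
diagnostics expose the identity `nonmetric R^2 = 1 - stress^2` and a
linear fit R^2 (squared correlation between monotone-fitted and
configuration distances).

Because beta-sim matrices are generally non-Euclidean while K-means is a
Euclidean method, cluster-number estimation runs on principal
coordinates with the Cailliez correction (`pcoa_cailliez()`, via
`stats::cmdscale(add = TRUE)`): the smallest constant `c` is added to
all off-diagonal dissimilarities so that the corrected matrix embeds
exactly; the full-space scores reproduce `d + c` to 1e-8, which the test
suite asserts on random Simpson matrices.

## Choosing the number of regions

The L-method fits two least-squares lines to the WGSS-versus-k curve on
either side of each candidate knee (candidates exclude the two first and
two last points so each segment keeps at least 3 points, giving residual
degrees of freedom `n - 2`). Segments are scored by the length-weighted
residual standard error; RSE rather than RMSE keeps curves of different
lengths comparable. Ties go to the smallest k (applied with a 1e-10
numerical tolerance, since exactly straight curves score every candidate
identically up to rounding). Because the knee position depends on the
largest k in the curve, `consensus_k()` repeats the search for every
maximum-k value from 4 (in practice 5, the smallest value admitting a
candidate knee) up to `max_k`, each run with its own derived seed
(`seed + max_k`, making runs order-independent), and returns the modal
optimum.

At the package's default experiment scale the scan is capped at
`max_k = 40` and uses the 10 leading principal-coordinate axes with 10
K-means restarts per fit; the exhaustive scan (`max_k` up to
`n_sites - 1`, all axes, 50 restarts) is available by argument but costs
roughly two orders of magnitude more K-means fits while the extra
high-k curves contribute knees far from any plausible optimum. These
problem sizes are also the ones at which the recovery experiments in the
test suite and `scripts/acceptance.R` run.

## Interpolation and the map

`idw_interpolate()` uses weights `d^-2` on great-circle (haversine)
distances in km; a cell within 1e-6 km of a site takes the site value
exactly, and the output is a convex combination of site values. The
function's default neighborhood is all sites, but `run_pipeline()` uses
the 12 nearest sites: with a study domain tens of site-spacings wide, a
global neighborhood lets far-away sites smooth away exactly the
between-region boundaries the map is meant to show, and local
neighborhoods are the standard GIS practice. Both the power and the
neighborhood are configurable.

`regionalize()` clusters every cell on its three interpolated ordination
coordinates only — geographic position is deliberately not a feature, so
spatial cohesion of the result is evidence about the compositional
surface, not an artifact of the algorithm. Labels are renumbered by
descending region size and cohesion is summarized per region as the
fraction of cells in the largest rook-connected component.
`rgb_compose()` maps the three axes to red/green/blue with one shared
scaling span, so channel spread stays proportional to axis spread; a
constant axis renders at mid-intensity 128.

## Spatial statistics

Moran's I uses the textbook cross-product form with expectation
`-1/(n-1)` and permutation p-values (999 or 199 permutations depending
on context, with the +1 correction). Correlograms use 14 equal-width
haversine distance classes by default and Holm-adjust the per-class
p-values, since the per-class tests are a family. MEMs follow the
Borcard et al. recipe: a Gabriel graph on haversine distances (augmented
with the minimum spanning tree so it is always connected), weights
`1 - (d/d_max)^2` with `d_max` the overall diameter of the point set —
scaling by the diameter rather than the longest edge keeps regular
lattices, whose edges are all equally long, non-degenerate — then
eigendecomposition of the doubly-centered weight matrix. Eigenvectors
with positive eigenvalue and significantly positive Moran's I
(one-sided permutation test, alpha 0.05) are selected. The pipeline caps
the selection at the 8 broadest-scale vectors: with permutation tests on
~n/2 candidate eigenfunctions a raw 0.05 threshold admits dozens of
vectors, and a multinomial model carrying them all would exceed its
AICc estimability bound `n > k + 1` at realistic sample sizes.

## Driver models

`fit_multinomial()` wraps `nnet::multinom` with internally standardized
predictors, a 1e-8 ridge (so separable data converge to a finite,
numerically zero-deviance fit) and the largest class as reference. The
log-likelihood is recomputed from fitted class probabilities, so the
reported deviance is unpenalized. The AICc parameter count is all free
coefficients, `(K-1)(p+1)`. Candidate models are every single predictor,
every named predictor family (soil, topography, current climate,
historical climate, footprint), the current-by-historical combination
and the full model, each with the selected MEMs appended so all
candidates control for spatial structure alike (a flag in
`build_candidates()` can omit them). Deviance is partitioned by the
standard three-fit subtraction: `unique_env = total - ED(mem)`,
`unique_mem = total - ED(env)`, `shared = ED(env) + ED(mem) - total`;
the three parts sum to the total exactly, and `shared` can be slightly
negative (suppression), which is a property of the partition, not an
error.

`permanova_2way()` is the McArdle-Anderson distance-based linear model:
Gower-centered inner-product matrix, sequential (Type-I) projections —
the physiognomic factor always enters first in classification
comparisons — and free permutation of the rows/columns of the distance
matrix. On a one-factor Euclidean distance matrix its pseudo-F equals
the classical ANOVA F to 1e-8 (asserted in the tests), and its type-I
error at alpha 0.05 is calibrated by simulation.

## Group structure

Sub-region floras are pooled by set union; UPGMA (average linkage, via
`hclust`) on the group-level Simpson matrix gives the dendrogram, and
node support resamples species columns with replacement — species are
the only exchangeable unit of a pooled group-by-species incidence —
recomputing the matrix and tree 1000 times by default (configurable;
pipeline default 200) and scoring each original bipartition by its
replicate frequency. Replicates that empty a group's species list are
redrawn and counted.

# The synthetic landscape: what it emulates and what it does not

The generator stands in for a compiled dry-forest floristic dataset
whose true structure is unknowable, replacing it with one whose
structure is known exactly.

*Landscape.* Annual rainfall follows an east-west gradient (about 400 to
1400 mm across a 60 x 60 grid of 2.5 arc-min cells) mixed with a
large-scale Gaussian random field and *terraced* into `planted_k`
equal-area plateaus separated by steep logistic steps; a 40-mm
spatially autocorrelated noise field sits on top. Mean annual
temperature is near 26 degrees C, lowered by elevation at the standard
6.5 K/km lapse rate. The derived Koeppen aridity surface AI =
MAP/(MAT+33) therefore carries `planted_k` distinguishable, contiguous,
equal-area bands, and the ground-truth sub-regions are exactly its
quantile slices. The terracing is deliberate: a featureless gradient
contains no true cluster number at all, so no method could recover one,
whereas the package's claim under test is recovery of structure that
exists. `generate_landscape()` refuses configurations whose plateau
separation falls below twice the rainfall noise sd — the planted count
would exceed the number of distinguishable aridity bands. With zero
noise the region borders are exact aridity-quantile contours. The 16
further bioclimatic layers are noisy affine companions of temperature or
rainfall; glacial-maximum counterparts add per-model smooth offsets
(three pseudo circulation models, averaged downstream into consensus
change surfaces); sand, cation-exchange capacity and human footprint are
random fields independent of the planted structure, which is what makes
them usable as nuisance drivers.

*Communities.* Each of 600 species gets an aridity optimum (uniform over
a slightly widened aridity range), a Gaussian niche breadth of 4-10% of
the aridity span — about one band wide at the default `planted_k = 5`,
so neighbouring bands share species and composition orders the bands —
a circular geographic range of radius 200-450 km, and a Bernoulli
occupancy cap `p_max = 0.6`. 150 sites are grid cells sampled without
replacement; realized incidence fill sits near 9%, mean site richness
near 40-50 species, and the locality filter re-applies the minimum
richness of 5.

*What it does not emulate.* Taxonomic noise (synonyms,
misidentification), herbarium collection bias, spatially varying
sampling effort, abundance, nestedness structure, and realistic
correlation between soil and climate are all absent. Passing recovery
tests therefore show that the chain of methods can recover known
banded structure at realistic sizes — not that real data meet these
assumptions. One consequence of the clean construction is worth
flagging: planted membership is a deterministic function of the aridity
surface, so a multinomial model carrying the aridity predictor can
classify the truth labels almost perfectly and its explained deviance
saturates near 100%, far above what noisy real data produce; the
meaningful driver-inference outputs are therefore the identity of the
AICc-best model and the relative unique/shared shares, not the absolute
deviance level.

# Recovery behaviour and known limitations

The end-to-end experiments (20 replicates per planted k in {3, 5, 7, 9};
60 x 60 grid, 150 sites, 600 species) recover the modal consensus k
within one of the truth in over 80% of replicates. Map recovery measured
as the adjusted Rand index between the K-means partition and the planted
bands is high at small k but declines as k grows: with 9 equal-area
regions on a 60 x 60 grid, 150 sites cannot localize the long
inter-region boundaries more precisely than roughly half the inter-site
spacing, and every boundary cell misassigned by the interpolation lowers
the ARI. Site-level recovery (clustering the sites' own ordination
scores, or reading the map at the site cells) stays substantially higher
than whole-map recovery at large k, which locates the loss in the
interpolation step, not the ordination or the clustering. This is an
information limit of the sampling density, not a tunable of the
implementation; the acceptance test for whole-map ARI is left asserting
the nominal 0.7 average and fails honestly at this sampling density,
with the per-k breakdown printed in its failure message.

Other limitations: the Gabriel-graph/MEM construction is O(n^3) in
sites and meant for hundreds, not tens of thousands, of localities;
PERMANOVA uses free permutation only (no restricted strata); the
multinomial models assume independent sites given predictors and MEMs;
and GeoTIFF I/O is out of scope — rasters are exchanged as ESRI ASCII
grids and PNG.

# Reproducibility

Every stochastic stage draws its own sub-seed from one master seed
(fixed offsets; see `phytoregion:::stage_seeds`), so stages can be
re-run in isolation and full pipeline reruns are bit-identical — the
run manifest records an md5 checksum per artifact and the smoke tests
assert rerun identity. Consensus runs derive per-run seeds as
`seed + max_k`, making the scan order-independent and trivially
parallelizable.
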