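# phytoregion

Quantitative floristic bioregionalization and environmental driver
inference for presence/absence community data.

Biogeographers and community ecologists working with compiled floristic
datasets — species lists for scattered localities across a region — face
two linked questions: *where are the natural sub-regions of the flora*,
and *what environmental factors explain them*? `phytoregion` implements
a complete, seeded, testable pipeline for both, built around the
methods standard in the bioregionalization literature:

1. **Turnover.** Pairwise Simpson dissimilarity between localities,
   `beta_sim = min(b, c) / (min(b, c) + a)` — pure species turnover,
   insensitive to richness differences and nestedness (species-poor
   sites nested in richer floras score 0).
2. **Ordination & mapping.** 3-D non-metric multidimensional scaling of
   the turnover matrix (Kruskal stress-1, Shepard diagnostics), axes
   interpolated to a regular grid by inverse-distance weighting and
   rendered as an RGB composition map.
3. **How many regions?** Cailliez-corrected principal coordinates feed
   the Salvador-Chan L-method (two-line piecewise fits to the K-means
   within-group-sum-of-squares curve, scored by residual standard
   error), repeated over every maximum-k value and summarized by the
   modal optimum.
4. **Regionalization.** K-means on the three interpolated axes at the
   modal k — no spatial features, so the spatial cohesion of the result
   is a finding, not an artifact. Cohesion is reported per region as the
   largest rook-connected component fraction.
5. **Drivers.** Site-level predictors (Koeppen aridity index
   AI = MAP/(MAT+33), glacial-interglacial aridity change and
   thermal/hydric envelope-change distances with circulation-model
   consensus, soil, topography, human footprint; 10-km buffer
   aggregation, |r| > 0.75 collinearity screen, VIF), Moran eigenvector
   maps as spatial controls, multinomial logistic candidate models
   ranked by AICc/wAICc, explained-deviance partitioning into unique
   and shared components, residual Moran correlograms, and two-way
   PERMANOVA comparison against alternative classification schemes.
6. **Group structure.** Pooled sub-region floras, UPGMA dendrogram on
   group-level Simpson dissimilarity with species-bootstrap node
   support, and the shared/exclusive species network.

Because real compiled datasets of this kind are rarely redistributable,
the package ships a first-class synthetic generator
(`generate_landscape()`, `generate_community()`): a seeded dry-forest
landscape whose aridity surface carries a known number of contiguous
bands, niche-structured communities sampled from it, and nuisance soil /
footprint layers independent of the truth — so every stage of the
pipeline can be benchmarked against a known answer.

## Worked example

```r
library(phytoregion)

land <- generate_landscape(landscape_config(planted_k = 5), seed = 11)
comm <- generate_community(land$stack, land$truth, seed = 12)
comm$occurrences
#> occurrence_table: 150 sites x 598 species, fill 8.9%

d <- simpson_dissimilarity(comm$occurrences)
d
#> dissimilarity_matrix: 150 labels, beta-sim range [0.293, 1.000], mean 0.898

ord <- nmds(d, seed = 13)
shepard_fit(d, ord)
#> Shepard fit: stress 0.0365, non-metric R2 0.999, linear R2 0.995

pco <- pcoa_cailliez(d)
cons <- consensus_k(pco$scores, max_k = 40, n_starts = 10,
                    n_axes = 10, seed = 14)
cons
#> k_consensus: modal k = 5 over 36 runs (max-k 4..40)
#> ks
#>  3  5
#>  2 34

axes <- lapply(1:3, function(j)
  idw_interpolate(comm$registry, ord$scores[, j], land$stack$geometry,
                  n_neighbors = 12))
part <- regionalize(axes, k = cons$modal_k, seed = 15)
part
#> region_partition: k = 5 on a 60 x 60 grid
#> cells per region: 774, 732, 717, 709, 668
#> largest-component fraction: 1.00, 1.00, 1.00, 0.90, 1.00

mclust::adjustedRandIndex(part$labels, land$truth$region_of_cell)
#> [1] 0.762
```

Reading the output: the turnover matrix is strongly structured (mean
beta-sim 0.898 with range down to 0.29), the 3-D ordination fits it
nearly perfectly (stress 0.037, i.e. 3.7 on the x100 convention), the
modal consensus recovers the planted five regions (34 of 36 max-k runs
agree), the partition is spatially cohesive without any spatial
constraint (largest-component fractions 0.90-1.00), and the map matches
the planted bands with an adjusted Rand index of 0.76.

`run_pipeline(run_config(seed = 1, out_dir = "out"))` executes the whole
chain — including predictors, MEMs, AICc model ranking, deviance
partition, PERMANOVA comparisons and the bootstrap dendrogram — and
writes ESRI ASCII rasters, GeoJSON regions, a PNG composition map, CSV
tables, a Newick tree and a JSON manifest with per-file checksums. A
thin command-line front end with verbs `simulate`, `regionalize`,
`drivers`, `compare` and `all` is installed at
`system.file("cli/phytoregion.R", package = "phytoregion")`.

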