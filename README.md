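# budprofiler

Unsupervised profiling of protein expression in budding-yeast fluorescence
micrographs. The package is for computational biologists who have (or want
to simulate) two-channel images — a red channel (RFP) carrying a
constitutive whole-cell marker, and a green channel (GFP) carrying a tagged
protein — and want, without training labels: identified cells with
confidence scores, interpretable per-cell expression features, cell-stage
("time") profiles built from bud size, and a clustered, enrichment-scored
map of the protein collection.

## What it computes

**Cell identification.** The RFP channel is segmented with a pseudo-2-D
hidden Markov model (Normal emissions for background and foreground, EM
along rows and along columns, posteriors averaged). Clumps are split by
robust regression of ellipses to clump contours — the algebraic error
$e(p) = (p-c)^\top A\,(p-c) - r^2$ under a constrained shape matrix $A$,
minimized with a redescending robust loss so each ellipse locks onto one
cell's arc — combined with watershed basins assigned to the nearest
ellipse. Mother–bud pairs are reciprocally the smallest/largest adjacent
shapes.

**Cell confidence.** Each object is scored by a two-component mixture
posterior

$$P(\mathrm{cell}\mid q) =
\frac{\rho\, N(q;\mu(s),\Sigma(s))}
     {\rho\, N(q;\mu(s),\Sigma(s)) + (1-\rho)\,U(q)}$$

over four quality measures $q$ (moment-fit density, contour/perimeter
ratio, circularity, mean RFP) with size-interpolated Normal parameters, a
uniform alternative spanning the collection extremes, and mixing parameter
$\rho$ estimated by soft-EM.

**Features and profiles.** Six features per cell: a size-normalized
GFP/RFP intensity ratio and five "morphological distances" — log ratios of
intensity-weighted expected distances (to cell center, protein mass
center, periphery, bud neck, and between proteins) computed for GFP
against the RFP marker. Bud area acts as a cell-stage clock
($t \propto \mathrm{area}^{3/2}$); confidence-weighted Gaussian-kernel
regression (bandwidth 1700 stage units) estimates each feature's mean and
variance at 10 stage keypoints, giving a 120-value time profile per
protein, with jackknife and stage-permutation checks.

**Clustering and enrichment.** Profiles are merged bottom-up with a
maximum-likelihood criterion (log-likelihood ratio of two diagonal
Gaussians versus their pooled merge), compared with Bhattacharyya
distances, and scanned for annotation enrichment with upper-tail
hypergeometric tests over every cluster in the hierarchy; the summary
statistic $S$ (sum of best $\log_{10} P$ per term) is calibrated with
topology-preserving permutation nulls, optionally constrained within
identical subcellular-localization label sets. Trees export to
TreeView-compatible CDT/GTR files.

A synthetic-scene generator with full ground truth (`simulate_micrograph()`,
`simulate_profile_collection()`, `evaluate_detection()`) makes every stage
testable without microscope data.

## Worked example

```r
library(budprofiler)

sim <- simulate_micrograph(scene_config(seed = 7, gfp_pattern = "nuclear"))
res <- process_micrograph(sim$micrograph, pipeline_config(), image_id = "demo")
cells <- dplyr::filter(res$cells, !artifact)
dplyr::select(cells, id, type, partner, area, cx, cy, bud_area)
#> # A tibble: 13 × 7
#>      id type   partner  area    cx    cy bud_area
#>   <int> <chr>    <int> <int> <dbl> <dbl>    <dbl>
#> 1     1 lone        NA   841  82.4 239.        NA
#> 2     3 mother       7  1656  26.6  61.4      405
#> 3     4 lone        NA  1262 124.   91.5       NA
#> ...

evaluate_detection(dplyr::select(cells, cx, cy, area), sim$truth)
#> # A tibble: 1 × 7
#>   recall n_truth n_detected n_matched mean_center_distance area_correlation
#> 1  0.846      13         13        11                 2.89            0.959
```

The 13 identified objects include one mother–bud pair (ids 3 and 7, bud
area 405 px — the stage covariate for that pair); 84.6% of the simulated
cells are matched within 10 px, at a mean center error of 2.89 px and an
area correlation of 0.959 against ground truth. The two misses are buds
below the 50-px artifact pre-filter.

`run_pipeline()` chains everything (simulation or TIFF input, confidence
model, features, profiles, clustering, enrichment) and writes TSV tables,
a TreeView CDT/GTR pair and a provenance log into an output directory;
`inst/cli/budprofiler.R` is a thin command-line wrapper over the same
functions.

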