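---
title: "Methods: unsupervised profiling of yeast protein expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unsupervised profiling of yeast protein expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

budprofiler analyzes two-channel fluorescence micrographs of budding yeast:
a red channel (RFP) carrying a constitutive whole-cell marker used for
segmentation and normalization, and a green channel (GFP) carrying the
tagged protein of interest. This vignette documents the models, the
parameters that matter, the synthetic-data generator that stands in for
microscope data, and the numerical choices made where the design was open.

## Cell identification

**Background correction.** `compute_background_image()` averages a
collection of RFP images pixel-wise; pixels with exactly zero variance
across three or more images are flagged as defective camera pixels, which
by construction report the same value in every frame. Subtraction floors at
zero. The pipeline driver subtracts the 5th percentile of the mean image (a
collection floor) rather than the full mean: with the handful of images a
desk-scale run processes, the cells themselves do not average out of the
mean image the way they do over a collection of thousands.

**Segmentation.** `segment_foreground()` models background and foreground
RFP levels as the Normal emissions of a two-state hidden Markov chain, run
once along rows and once along columns (the pseudo-2-D construction), with
full Baum-Welch EM in each direction and the per-pixel foreground posterior
taken as the average of the two. The chain's run-length prior is what
suppresses punctate noise. EM starts from a median split of the intensities
with 0.95 self-transitions and stops when the relative log-likelihood
change falls below 1e-6 (cap 200 iterations). The foreground state is, by
convention, the higher-mean state. Posteriors are invariant to adding a
constant to the image, since Normal EM is shift-equivariant.

**Edge-distance map.** For quality measures, contour extraction and the
distance-to-periphery feature, `edge_distance_map()` computes each pixel's
expected distance to background over a move set of unit, diagonal and
knight steps (lengths 1, sqrt(2), sqrt(5)). Uncertainty enters twice: a
pixel's own foreground posterior scales its distance, and the onward
distance through a neighbor at step length *d* is discounted by the
probability of remaining in the foreground state over that step, taken
from the HMM transition matrix raised to the power *d* (eigendecomposition
handles the non-integer powers). The recursion

    E(p) = f(p) * min_q [ d(p, q) + (T^d)_ff * E(q) ]

is a monotone fixed point solved by value sweeps; with hard posteriors and
identity transitions it reduces exactly to Dijkstra shortest-path distance
under the same move set, which is how the tests pin it down. The image
border is treated as certain background: objects touching the border are
low-confidence in any case, and the convention gives the map a zero level
everywhere it needs one.

**Contours and robust ellipse regression.** Contour pixels are foreground
pixels with edge distance at most the contour thickness (default 5 px).
Within each 8-connected clump, `fit_ellipses_robust()` fits one ellipse at
a time. The ellipse parameterization uses a center, an equal-area scale
`r` (so `pi * r^2` is the area for every eccentricity), an eccentricity
parameter and an orientation; the constrained shape matrix bounds the
minor/major axis ratio below by `ratio_min` (default 0.5), so hyperbolae
and needle ellipses are unrepresentable. The working residual is the
algebraic error divided by `2r`, which is the first-order signed geometric
distance to the curve; on that scale the robust residual scale `sigma`
defaults to half the contour thickness, because band pixels lie within
half a thickness of the band mid-line.

Two choices here were forced by clump geometry, and are worth recording.
First, the robust loss is redescending (Geman-McClure,
`rho(e) = (sigma^2/2) e^2 / (sigma^2 + e^2)`, IRLS weight
`1/(1+(e/sigma)^2)^2`) rather than a Cauchy-type loss: an unbounded loss
lets an ellipse wrapped around the whole clump envelope outscore every
single-cell ellipse, while a saturating loss makes pixels that belong to
other cells contribute a constant, so per-cell minima dominate. Second,
among converged candidates (circles through 3 random contour pixels,
rejected when they escape the clump's clamping rectangle or sit on a
background-centered pixel), selection maximizes contour *completeness* —
the fraction of the ellipse's expected `2 pi r * thickness` band covered
by low-residual pixels — rather than the raw objective, because a large
ellipse that grazes many arcs still accumulates less loss than a small
ellipse explains. Accepted ellipses consume contour pixels within one
thickness of the curve; ellipses narrower than 3 px or explaining under
10% of their expected pixel count are rejected (their pixels are still
consumed, so the iteration terminates). The fit targets the band mid-line;
accepted ellipses are then expanded outward by the mean edge-depth of
their consumed pixels minus half a pixel, which makes the reported `r` the
cell-boundary radius.

**Shapes and types.** `watershed_basins()` labels every foreground pixel
with the local intensity maximum it reaches by steepest ascent (plateaus
tie-break toward the lowest pixel index, so labeling is deterministic).
Basins are assigned to the ellipse whose algebraic error at the basin's
brightest pixel is smallest in absolute value; unions of same-ellipse
basins are the cell *shapes*, and basins in clumps with no accepted
ellipse stay in an artifact pool. Mother-bud pairs are reciprocally the
smallest and largest adjacent shapes, with the additional rule that a bud
may not have a neighbor smaller than itself; everything else is lone.
Adjacency means sharing at least one 8-connected cross-boundary pixel
pair. Exact size ties (possible on synthetic data) break by ellipse-fit
residual and then by shape id, and are flagged. The bud neck is the set of
boundary pixels between the paired shapes; its position is their mean
coordinate. Two independent G1 cells that touch are deliberately kept as a
pair — the size relation, not provenance, defines the pairing.

## Cell confidence

Each shape gets a closed-form moment ellipse (`moment_ellipse_fit()`):
centroid, semi-axes `2 * sqrt(eigenvalue)` of the second central moment
matrix, and density `D` = pixel count / fitted ellipse area. Shapes with
fewer than 5 pixels, `D >= 1`, area below `min_area` (default 50 px) or
minor semi-axis below `min_axis` are routed to the artifact class before
any modeling. Four quality measures follow:

* `q_density = log(1 - D)` — bitmap cells have `D` just below 1;
* `q_perimeter` — log ratio of the count of perimeter pixels (3 or more of
  the 8 neighbors in background) to the Ramanujan first approximation of
  the moment ellipse's perimeter. The 3-of-8 rule counts about two thirds
  of a digitized smooth boundary, so circular objects sit near
  `log(2/3)` rather than 0; the model learns this offset, and only the
  spread matters;
* `q_circular` — log coefficient of variation of the per-pixel sum of
  distance-to-center and edge distance, which is exactly the radius (zero
  variance) for an ideal circle; the CV is floored at 1e-3 so near-perfect
  circles do not produce `-Inf`;
* mean RFP intensity.

The cell class is a diagonal Normal over the four measures whose
parameters interpolate linearly between 7 size bins (equal-quantile
anchors of the labeled-cell sizes; empty bins borrow their nearest
neighbor and are flagged; per-measure sds are floored at 1e-3 of the
training range). The alternative is a uniform density spanning the
collection-wide extremes of each measure. The posterior that an object is
a cell follows Bayes' rule with mixing parameter `rho` estimated by
soft-EM — `rho` iterates to the mean posterior with all other parameters
held fixed. A mother-bud pair's probability is the product of its two cell
probabilities, and a paired cell is partially assigned to the lone class
with weight `cell_p * (1 - partner_p)`. Downstream estimates weight cells
by these probabilities instead of thresholding, which keeps the small buds
that anchor the early cell stages.

## Expression features

Six features per cell. The intensity feature is total GFP divided by the
size-expected total RFP, where expected mean RFP as a function of area is
a continuous 3-segment piecewise-linear fit (`fit_rfp_size_model()`,
breakpoints free, profiled linear least squares inside a Nelder-Mead
search over breakpoint placements, end segments extrapolating). The five
morphological distances treat normalized pixel intensity in a channel as a
probability distribution over pixel coordinates and compare an expected
geometric distance under the GFP distribution with the same quantity under
the RFP marker distribution, as a natural-log ratio: distance to the cell
center, to the channel's own mass center, to the cell periphery (via the
edge-distance map), to the bud neck (mother-bud pairs only; recorded
missing for lone cells rather than imputed), and between proteins, where
the numerator is the GFP-GFP pair expectation and the denominator the
GFP-RFP cross expectation. All five are zero when the two spatial
distributions coincide and are invariant to rescaling either channel;
coordinates are pixel centers; negative background-subtracted intensities
clip to zero before normalization. The pair expectations are computed as
exact double sums.

## Time profiles

Bud area is the cell-stage clock: under constant bud-volume growth, time
scales with `area^(3/2)` (the exponent is a parameter). Per protein, each
mother-bud pair contributes its 12 feature values (6 per cell role) at its
stage, weighted by the pair probability. At 10 equidistant keypoints
(spanning the 1st-99th percentile of observed stages — absolute keypoint
values would be tied to one pixel scale), a Gaussian kernel of bandwidth
1700 stage units computes weighted means and plug-in weighted variances;
the 120 means plus 120 variances form the protein's time profile. The
bandwidth default follows the stage transform's native scale and is
exposed, since its unit changes with the stage exponent. Keypoints where
the total kernel mass falls below 1e-8 are flagged unreliable.

Robustness is assessed two ways. `jackknife_profile_variance()` reports
the leave-one-pair-out variance of each keypoint mean as a fraction of the
feature's total weighted cell-to-cell variance. `stage_permutation_test()`
permutes the stage covariate across pairs (features and weights stay with
their pair), recomputes the keypoint means, and reports two-sided add-one
empirical tail probabilities (2.5% per tail at the 5% level; a one-sided
option is exposed). Under the null, about 5% of keypoints land in the 5%
tails — 3 expected of 60 tested points, 1 of 20.

## Clustering and enrichment

A profile is summarized as a diagonal Gaussian with member count.
Merging is size-weighted moment matching, including the between-means
variance term, so a fold over any merge order equals the pooled moments of
the raw membership. The merge criterion is the log-likelihood ratio of two
Gaussians versus the merged single Gaussian, which for diagonal
covariances reduces to `(n/2) sum log var_merged - (n1/2) sum log var1 -
(n2/2) sum log var2`: non-negative, zero only for identical components.
Covariances stay diagonal after merging — the initial (LOESS) variances
are diagonal, determinants then factorize, and a full covariance would be
unidentifiable for singleton clusters. Agglomeration greedily merges the
lowest-scoring pair (ties to the lowest index pair, seedless); Euclidean
and correlation metrics with complete linkage are available behind the
same interface as robustness checks, delegated to `stats::hclust`.
Unreliable profile entries are imputed with the profile's mean and an
inflated variance before clustering, and flagged. Trees export to
TreeView-compatible CDT/GTR files; display order puts the larger child
first, with no optimal leaf ordering.

Class profiles merge all proteins sharing an exact localization label set.
Classes are compared with the Bhattacharyya distance for diagonal
Gaussians, which unlike the merge criterion does not grow with member
counts; group structure is tested by comparing mean within-group to mean
between-group distances under permutation of the class-to-group
assignment. Annotation enrichment scans every internal node of size at
least 2 for the smallest upper-tail hypergeometric log10 P per term
(universe = the clustered proteins), reports Bonferroni corrections as
`+log10(m)` in log scale, and summarizes a family of terms by S, the sum
of best log10 P values. Significance of S comes from topology-preserving
permutations of the leaf-to-protein assignment — unconstrained, or
constrained to permute only proteins with identical localization label
sets, which preserves localization-driven enrichment under the null and
so isolates enrichment beyond localization. Both a Z score and an add-one
empirical p are reported, since the null need not be Normal.

## The synthetic-scene generator

`simulate_micrograph()` renders what the identification stages assume:
ellipsoidal cells with per-cell RFP plateau levels drawn from a Normal
distribution, a radial dome profile (interior brighter than the rim) so
each cell carries exactly one intensity maximum, a 2-px Gaussian blur for
the optical roll-off, 1-px dim gaps between touching cells (so inter-cell
boundary pixels are dimmer than both interiors and watershed basins split
there), mothers with attached buds spanning a wide bud-size range,
optional vacuole dimming, Gaussian background noise, and artifact objects
(corner noise, ruptured envelopes, dim blobs, defective pixels) with
masks. GFP patterns per scene: uniform, nuclear disc, peripheral ring,
bud-neck spot, punctate, or stage-switching (nuclear below a bud-size
quantile, uniform above). Values clip to the 12-bit range and are stored
in 16-bit containers on disk.

Three generator choices are deliberate. Scene density defaults to about
three times the field density of a typical high-resolution acquisition
(8 primary cells per 256 x 256 field, against roughly 82 cells per
1331 x 1017 frame), dense enough to produce multi-cell clumps without
making chains of 6-8 cells — whose interior members expose no contour arc
at all — the typical case. Nominally isolated cells are placed at least
12 px apart, because the blur halo plus the HMM's run-length smoothing
bridge smaller gaps into de-facto clumps. And ground-truth types are
derived by applying the reciprocal smallest/largest adjacency rule to the
generative geometry, so two independent cells that touch are recorded as
a pair — the same convention the identification uses.

What the generator does not emulate: a realistic point-spread function,
3-D defocus, photobleaching, camera vignetting beyond the flat background,
or biologically structured cell-to-cell correlation in expression.
Passing tests on this generator show the algorithms recover the structure
they model; they do not certify performance on real microscope data.

`simulate_profile_collection()` draws 120-value profiles as class means
plus independent Gaussian noise, for testing the clustering and
enrichment layers with known labels. `evaluate_detection()` matches truth
to detections greedily by increasing center distance with a one-to-one
constraint within a 10-px radius and reports recall, center-error and
area-correlation statistics, plus the fraction of unmatched detections
sitting on artifact pixels.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: constant images are rejected in
segmentation; all-background images give empty contours; contours with
fewer than 3 pixels, or objects narrower than 3 px, produce no ellipse;
zero RFP inside a cell (a ruptured-cell signature) raises a classed
error; all-zero GFP records the feature as missing with a reason; the
jackknife requires 3 pairs; empty confidence bins borrow and flag.
Permutation p-values use the add-one rule `(b + 1) / (B + 1)` so they are
never zero.

The test suite and the acceptance script run everything at desk scale:
scenes of 256 x 256 with 8 primary cells, 3-5 scenes per run, 200-1000
null profiles at 200 permutations, 2000-object mixtures, and 60-100
profile collections for clustering — sizes chosen so the full suite
completes in minutes while every statistical check retains enough
resolution for its stated tolerance.

## Known limitations

Interior cells of large clumps expose no contour arc and cannot be seeded
by the ellipse stage; their basins attach to neighbors (the shape-based
recovery the method relies on, but also its main failure mode). Buds
below the artifact pre-filter area are deliberately dropped, which
truncates the earliest cell stages when buds are very small. The
Ramanujan perimeter approximation degrades for extreme axis ratios
(0.4% low at ratio 10:1 against the exact arc length), well inside the
regime the axis-ratio bound permits. The stage covariate is a monotone
transform of bud area, not physical time; bandwidth and keypoints are
expressed in its units and change meaning if the exponent changes.
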