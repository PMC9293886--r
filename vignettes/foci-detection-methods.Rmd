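---
title: "Contour-loop foci detection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contour-loop foci detection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(puncta)
```

## The problem

Stress granules and similar cytoplasmic foci in yeast fluorescence
microscopy have low signal-to-background contrast, irregular shapes, and sit
on a cytoplasmic background that varies from cell to cell (vacuoles carry
almost no signal at all). Global or per-cell thresholds therefore perform
poorly, and human annotators are strikingly inconsistent, both between users
and against themselves. `puncta` implements a detection pipeline whose
*candidate* definition is parameterless up to two physical length bounds,
whose *final outline* is parameter-free, and whose *selection* step is
learned from a user's labels so it can be replayed consistently over
arbitrary batches.

## Candidates as nested contour loops

Treat the (per-cell, min–max normalized) intensity patch as a height field.
Closed iso-intensity contours — found to sub-pixel precision with the
marching-squares algorithm (`grDevices::contourLines`) — either nest or are
disjoint; they can never cross. A *focus candidate* is a pair of closed
loops $(C_k, C_j)$, an outer loop at intensity $I_k$ and an inner loop at
$I_j > I_k$ contained in it, with perimeter bounds
$\mathrm{len}(C_j) \ge L_\min$ and $\mathrm{len}(C_k) \le L_\max$. The
bounds are the only detection parameters; they are denominated in nm and
converted through the pixel size (default 40.7 nm/px), so they transfer
across images of equal magnification. Concretely, the inner loops are the
*innermost* loops of length at least $L_\min$, each paired with the longest
containing loop of length at most $L_\max$; an outer loop containing
several inner loops yields one candidate per inner loop. No shape model is
implied, so elongated foci are handled exactly like round ones, and clumped
foci need no watershed-style splitting: nearby candidates merge or remain
separate on their own (below).

## The parameter-free final outline

The final outline of a candidate is the contour at the intensity where the
*curvature* (second derivative) of the radial intensity profile is maximal
— not the inflection point, which exists for some peak shapes (Gaussian)
but not others (cone-like profiles) and tends to sit too tight around the
peak. Since contours are not circles, the radial profile is reconstructed
from the contour *area function*: sampling the area $a(I)$ of the contour
containing the inner loop at `n_eval` intensities in $[I_k, I_j]$ gives a
monotone piecewise-linear function, and

$$ r(I) = \sqrt{a(I)/\pi} $$

is the equivalent-radius profile whose inverse $I(r)$ is differentiated
twice numerically. For a circular focus this is exact; otherwise it is the
natural approximation. For a Gaussian profile
$I(r) = A e^{-r^2/2\sigma^2}$ the curvature maximum sits at
$r = \sqrt{3}\,\sigma$, which is the analytic anchor used throughout the
tests.

Numerical choices (all defaults, none load-bearing for the result within
the tested tolerances):

* `n_levels = 64` marching-squares levels for candidate extraction and
  `n_eval = 32` area samples — enough that the level grid, not the sampling,
  limits resolution.
* $I(r)$ is fitted with a low-rank smoothing spline (6 degrees of freedom)
  whose analytic second derivative is evaluated on a dense radius grid.
  Discrete curvature estimates are noisy at the few-pixel scale of yeast
  foci: the areas measured from polygonized contours carry a pixel-level
  wiggle whose induced curvature is comparable to the real feature for
  $\sigma \approx 2$ px, and a smooth unimodal decay has few genuine
  degrees of freedom, so a low-rank fit recovers the argmax where
  finite-difference schemes on interpolated samples do not.
* The spline's unconstrained boundary zone (outer 5% of the radius span at
  each end) is excluded from the argmax; the curvature maximum is an
  interior feature of the profile by construction ($I_k < I_{opt} < I_j$
  is enforced).
* Ties in the curvature maximum resolve to the lower intensity, i.e. the
  larger contour, consistent with preferring the curvature maximum over the
  (tighter) inflection-point boundary.
* Fewer than 5 valid area samples (contours broken by the cell mask) fall
  back to the midpoint intensity and set a warning flag.

Two candidates under one outer loop merge exactly when their final contours
coincide, which is detected by mutual containment of the partners' inner
loops; because contours never cross, the surviving outlines of a cell are
always pairwise disjoint. A fixed `area_scale` factor can grow or shrink
all final outlines radially about their centroids for users whose size
perception differs systematically from the curvature-maximum rule.

## Cell segmentation from brightfield

Fluorescence background is unreliable for delimiting cells, so boundaries
come from brightfield images: (1) Frangi vesselness (implemented in-package
from the Hessian-eigenvalue formulation, scales 1–2 px, relative threshold
0.2, with a flag for dark-on-bright rings) gives a ridge mask; (2) blobs
failing area/eccentricity/solidity bounds are removed; (3) the mask is
thinned to a skeleton (Zhang–Suen); (4) every pixel whose
distance-to-skeleton lies in $[r_\min, r_\max]$ (cell-size bounds, in nm)
is scored by the mean squared distance of a direct least-squares ellipse
fit to the surrounding skeleton points — the mean rather than the plain sum
so scores are comparable between candidate points with different numbers of
nearby skeleton points; candidates whose surrounding skeleton covers less
than 75% of 16 angular bins are discarded as open outlines; (5) local
minima of the (lightly smoothed) score map are cell-center hypotheses, and
their ellipses are snapped to the image with a greedy active contour:
per-vertex search along the local normal (±3 px in 0.5 px steps) optimizing
external energy — by default the smoothed image intensity itself, because
cell edges in brightfield render as bright crests where the gradient
magnitude *vanishes*; a gradient-magnitude mode is available — plus
continuity and curvature penalties (weights 0.15). Collapsed, exploded or
overlapping outlines are flagged and dropped rather than aborting the
image. The whole chain is deterministic, and an externally produced binary
or label mask can bypass it entirely (`outlines_from_mask()`).

## Fluorescence preprocessing

Stacks are max-projected and denoised with classic non-local means
(offset-vectorized with integral-image patch sums; strength is relative to
the image range, 0 = identity). Denoising runs on the full projected image
before cells are extracted. Per cell, the patch is min–max normalized over
in-mask pixels; contouring and feature extraction use normalized values,
while every exported brightness is taken from the untouched raw patch. For
contouring, out-of-mask pixels are filled with the in-mask minimum so that
marching squares cannot fabricate loops hugging the membrane — the choice of
fill rule only matters within one contour level of the cell boundary and is
covered by tests.

## Features and classification

Each focus yields 12 numbers in 8 groups: intensity (max/min/mean inside
the outline), geometry (area, eccentricity from rasterized second moments,
solidity as area over convex-hull area), relative size (focus/cell area),
brightness ratios of the predicted and of the outer contour to the center
intensity (center = maximum inside the inner loop; the ratios are clamped
to $(0,1]$), their absolute difference, the centroid distance to the cell
centroid normalized by the cell's equivalent radius, and a brightness rank
inside the cell mapped to $[0,1]$ (a lone candidate ranks 1). Because
features are computed on per-cell normalized patches they are invariant to
affine rescaling of raw intensities.

The feature matrix is whitened (per-feature z-score) and rescaled to
$[0,1]$; the fitted scaler is stored inside the model and reapplied
verbatim at prediction time. Classification uses an RBF-kernel SVM
(`e1071`/libsvm; defaults $C = 1$, $\gamma$ = `"scale"`), evaluated with
the Matthews correlation coefficient — the right score for the heavy
class imbalance of foci candidates — and with its sixfold cross-validated
mean (CVMCC) whenever a model is scored against its own training data. A
logarithmic grid search ($C \in 10^{-3..3}$, $\gamma \in 10^{-8..1}$)
maximizes CVMCC, with ties preferring smaller $C$ then smaller $\gamma$;
on separable data it improves only marginally over the defaults. The
random-quantifier baseline re-draws each cell's selection count uniformly
at random and averages the MCC over 50 repetitions, anchoring the
chance level (≈ 0) of any selection profile. Datasets without negative
examples (bright P-bodies, spindle pole bodies…) cannot train an SVM; the
threshold pipeline (`threshold_classify()`, an axis-aligned conjunction of
per-feature bounds) covers them. Models serialize to a single JSON file —
support vectors, coefficients, scaler, settings — so a trained model can be
shared and replayed elsewhere; a round-trip test guarantees identical
predictions after reload.

Folds are label-stratified and seeded; the MCC returns 0 when a denominator
factor vanishes (the standard convention) and errors only on an empty
confusion matrix.

## Colocalization

Between two channels extracted with the *same* cell outlines: Pearson
correlation over in-mask raw pixels per cell and over in-outline pixels per
focus; for every focus pair, centroid distance, boundary distance (minimum
edge-to-edge distance over both polygons, 0 when they touch or overlap) and
overlap area with per-partner fractions; nearest neighbors by centroid
distance. Overlap uses exact Sutherland–Hodgman clipping when both
polygons are convex and a 0.25 px supersampled point-in-polygon count
otherwise (no polygon-clipping library is required). Distances and areas
are reported in px and in nm via the pixel size. Trend fitting offers
linear, power (log–log) and exponential (semi-log) least squares with
$R^2$ evaluated on the original scale. Manders coefficients and Costes
randomization are deliberately out of scope.

## The synthetic generator

`synthetic_scene()` renders the study conditions for every test: elliptical
cells whose brightfield boundary is a Gaussian ridge crest (width 1.5 px)
over a flat background; cytoplasmic fluorescence at `background_level`
(default 0.25 in unit intensity) with near-dark vacuole discs; foci as
radial Gaussians $A e^{-r^2/2\sigma^2}$ (a cone profile without an
inflection point is available for edge-case tests) distributed across z by
a Gaussian weight whose maximum is 1, so the max projection recovers
`background + amplitude` exactly; additive Gaussian noise (Poisson shot
noise behind a flag). `random_scene()` draws non-overlapping cells on a
jittered grid with semi-axes 13–22 px, Poisson-distributed foci of
$\sigma \in [2, 4]$ px and amplitudes 0.15–0.6 — peak-to-background ratios
of 1.6–3.4, spanning the ambiguous regime where thresholding fails and the
clearly-bright regime where it works. The default pixel size is
40.7 nm/px. Every rendered focus carries its ground truth, including the
analytic curvature-maximum radius $\sqrt{3}\sigma$.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: no point-spread function or deconvolution artifacts,
no spatially correlated noise, no camera bit-depth effects beyond scaling,
no clumped or non-elliptical cells, no autofluorescence gradients. The
fixtures validate the algorithmic contracts (recovery of known geometry,
invariances, determinism), not end-to-end accuracy on microscope data.

```{r example, eval = FALSE}
scene <- random_scene(n_cells = 5, foci_lambda = 2, seed = 1)
bf <- make_brightfield(scene)
fl <- make_fluorescence(scene, z_slices = 10)
outlines <- segment_cells(bf$image, segmentation_params())
img <- denoise_nlm(max_project(fl$stack), strength = 0.05)
regions <- extract_cells(img, outlines)
det <- detect_foci(regions[[1]], L_min_nm = 250, L_max_nm = 2500)
features <- extract_features_cell(det$foci, regions[[1]])
```

## Problem sizes and determinism

The test fixtures use 80–200 px images, up to ten cells, and labeled
feature sets of up to 600 candidates with sixfold cross-validation — sizes
at which every analytic oracle (circle perimeters, level-set areas,
$\sqrt{3}\sigma$ radii, saddle levels of two-Gaussian mixtures,
brute-force grid searches) is computable exactly or to controlled
precision. All randomness flows through explicit integer seeds
(`with_seed()` restores the caller's RNG state), segmentation and
detection are seed-free and fully deterministic, and pipeline outputs are
written with fixed JSON serialization so equal configuration hashes yield
byte-identical files.

## Known limitations

* The active-contour modification used for boundary snapping in the
  original interactive tool is unpublished; the greedy normal-search snake
  here is a documented stand-in with the same interface and acceptance
  behaviour on synthetic data.
* Foci smaller than ~2 px σ are at the mercy of the level grid; the
  curvature-maximum radius tolerance (10%) reflects that.
* Cells must be approximately elliptical and non-overlapping; merged cells
  are rejected rather than split.
* Contouring operates on 2-D max projections; no 3-D outlines.
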