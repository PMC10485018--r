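---
title: "Supervised dynamic sampling for scanning microscopy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised dynamic sampling for scanning microscopy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sladscan)
```

## The problem

A scanning microscope visits points on a grid and records one signal per
point — here, the intensity diffracted into a detector region of interest,
which assembles into a dark-field image of the specimen. Full pointwise
scans are slow and dose-heavy, while the information usually concentrates in
sparse regions: flake boundaries, bubbles, defects. `sladscan` implements a
supervised dynamic-sampling decision engine (the SLADS-Net family) together
with everything needed to run it closed-loop without hardware: a simulated
instrument, reconstruction and scoring, batch selection, scan-route
optimization, and center-of-mass post-analysis of per-point diffraction
patterns.

## The decision model

After $k$ measurements $Y^k = \{(s^i, a_{s^i})\}$, the image estimate
$\hat A^k$ is computed by inverse-distance-weighted (IDW) interpolation over
the $k$-nearest measured neighbors. The distortion is the squared L2
difference $D(A, \hat A^k) = \lVert A - \hat A^k\rVert^2$, and the reduction
in distortion (RD) from measuring a new location $s$ is
$R^{k,s} = D(A, \hat A^k) - D(A, \hat A^{k,s})$. The scanner cannot evaluate
$R^{k,s}$ (it involves the unknown ground truth), so it ranks candidates by
the *expected* reduction in distortion (ERD), predicted by a regression
$\bar R^{k,s} = g(v^{k,s})$ on a six-dimensional feature vector describing
the local measurement state:

* `grad_x`, `grad_y` — central-difference gradients of the reconstruction at
  the candidate pixel;
* `sigma1`, `sigma2` — inverse-distance-weighted mean absolute and squared
  deviations between the nearby measured values and the estimate at the
  candidate, restricted to a radius $r$ (falling back to the $k = 10$
  nearest);
* `nearest_dist` ($L$) — distance to the closest measured point;
* `density` ($\rho_r$) — measured fraction of the pixel disc of radius $r$.

The regressor is a fixed random-Fourier-feature map from 6 to 50 dimensions
(approximating a Gaussian kernel) followed by a fully connected network with
five hidden layers of 50 ReLU units and a linear scalar output, trained for
100 epochs with Adam at learning rate 0.001 on mean squared error.

### Numerical choices that the method text leaves open

The feature names fix the semantics but not the formulas; the definitions
above follow the conventions of the original supervised-dynamic-sampling
lineage. Beyond that, several constants had to be pinned:

* **Neighborhood radius.** $r = \max(1,\, 0.25\sqrt{N / k_{\text{meas}}})$ —
  a quarter of the mean inter-measurement spacing scale — recomputed each
  iteration and exposed in `feature_config()`.
* **Kernel bandwidth.** Features are standardized with constants frozen from
  the training set, and the Gaussian kernel uses $\gamma = 1/24$: the median
  heuristic for 6 standardized dimensions, where the expected squared pair
  distance is about 12. A unit bandwidth on standardized features makes the
  kernel effectively a delta — the 50 random features degenerate to
  quasi-orthogonal phases and the network fits the training set without
  generalizing; we verified both regimes and kept the median-heuristic value.
* **Training target.** The exact windowed RD (available as
  `compute_rd()` / `compute_rd_map()`, and checked against brute-force
  recomputation in the tests) is an unbiased but noisy target: with $k$-NN
  IDW, adding one point displaces discrete neighbor sets, so the exact RD
  carries heavy-tailed, signed noise that no function of the six features can
  express. The default training target is therefore the classic approximate
  RD: the Gaussian-weighted local squared-error mass around the candidate
  with kernel width $L / c$. It is non-negative, smooth, and the quantity the
  supervised-sampling lineage actually regresses on. The divisor $c = 1$ was
  selected by rank-correlation validation against the exact RD on held-out
  states of the *training image only*, keeping the selection sample-agnostic.
  `build_training_set(..., target = "exact")` retains the unbiased variant.
* **RD locality window.** RD is evaluated in a square window of half-width
  $3L$ around the candidate; an added IDW point influences a region that
  scales with its nearest-neighbor distance, and on small grids the windowed
  and full-image values agree closely (tested).
* **Degenerate neighborhoods.** At prediction time, a pixel whose features
  are exactly degenerate — zero gradients and zero deviation between the
  estimate and every nearby measured value — receives an ERD of exactly 0
  without consulting the network: its local model is perfectly interpolated
  and locally constant, so there is nothing to improve. This mirrors the
  exact-hit shortcut in the interpolator and keeps large homogeneous regions
  (e.g. empty substrate) tied at zero instead of carrying network
  approximation noise. Training targets are never clipped; only selection
  scores are.
* **Optimization.** Minibatches of 1024 keep the per-step overhead of the
  CPU implementation low; initialization is He-scaled Gaussian, and all
  randomness (weights, shuffling, mask draws) derives from integer seeds, so
  training is bit-reproducible.

### Sample-agnostic training

The shipped configuration trains on the bundled 128×128 copy of the standard
public-domain "cameraman" photographic test image
(`load_training_image()`), which has no relation to microscopy — the point
being that one generic model transfers to unseen subjects. The training set
pairs features with RD targets over ten coverage levels from 1% to 80%, ten
random masks per level, up to 2000 candidate pixels per mask (about 200,000
pairs, a few minutes of CPU). `generic_training_image()` provides a fully
synthetic alternative scene (gradient + geometric shapes + mild texture) for
environments where even the bundled photograph is unwanted.

## The acquisition loop

`run_fast_scan()` measures a deterministic 2-D Hammersley low-discrepancy
set covering 1% of the grid, then iterates: IDW reconstruction → ERD
prediction at every unmeasured pixel → selection of the 50 highest-ERD
pixels (descending, ties broken lexicographically) → route optimization →
simulated measurement. Batching amortizes the decision cost; 50 points per
batch is the default. The route optimizer builds an open path from the
better of the selection order and a greedy nearest-neighbor construction,
then applies 2-opt reversals and or-opt relocations to local optimality —
deterministic, never longer than the selection order, and within 10% of the
exhaustive optimum on small instances (tested over 20 random 7-point
configurations).

Stopping is `coverage_only` at 35% by default, mirroring the practice of
running an exploratory scan well past visual stabilization;
`stopping_rule("erd_plateau", window, rel_tolerance)` implements the natural
numerical criterion — stop when the summed ERD's relative change over the
trailing window falls below the tolerance. Per-iteration metrics (NRMSE,
SSIM, total ERD, route lengths) are recorded against the ground truth on the
cheap in-loop IDW estimate; final images use biharmonic inpainting, and
snapshots of the measurement state can be stored at requested coverages
(`checkpoint_coverages`) for later analysis.

## Reconstruction and scoring

In-loop reconstruction is Shepard (IDW) interpolation with power 2 over the
10 nearest measured points, with exact pass-through at measured pixels and a
k-d tree for neighbor search. On integer grids, distance ties at the
neighbor-set boundary are common and tree libraries break them arbitrarily;
`sladscan` re-breaks ties deterministically on (distance, pixel linear
index), which makes reconstructions bit-reproducible and lets the tests
compare against brute-force oracles at 1e-10.

Final images solve the variational biharmonic (thin-plate) problem: minimize
$\lVert D_{xx}u\rVert^2 + 2\lVert D_{xy}u\rVert^2 + \lVert D_{yy}u\rVert^2$
subject to exact interpolation of the measured pixels, via a sparse Cholesky
factorization. Affine images have zero energy, so linear ramps are
reproduced exactly; with fewer than three measured points the affine part is
unpinned and the implementation falls back to IDW.

Scoring uses NRMSE (RMSE over the ground-truth range; the normalizer is not
fixed by convention, and range-normalization matches the [0, 1] intensity
scale) and the standard mean local SSIM with 7×7 uniform windows, unbiased
covariance normalization and data range 1 — verified in the tests against a
frozen reference value computed with scikit-image.

## The simulated instrument

`generate_flake_image()` draws elliptical flakes at discrete thickness
levels (brighter = thicker) on an exactly zero background — flake-free
substrate diffracts nothing into the ROI — and depresses annular bubble rims
by a configurable contrast, emulating how film curvature tilts the lattice
out of the diffraction condition. The default target coverage is 30% of the
grid, a sparse-feature regime. `generate_diffraction_stack()` gives every
scan pixel a 2-D Gaussian detector pattern whose total intensity equals the
dark-field value and whose center is displaced from the nominal position by
`shift_gain` times the gradient of a spherical-cap height field over each
bubble — the simplest model that produces the sign-reversing center-of-mass
signature across a bubble. Patterns are renormalized after discretization,
so ROI integration over the full detector reproduces the generating image
exactly. What the simulator does *not* emulate: diffraction geometry (Ewald
sphere, peak asymmetries), detector noise (available separately through
`noise_model()`), hot pixels, or drift — so passing tests demonstrate the
decision logic and analysis chain, not instrument realism.

Measurement noise is configurable (`none`, additive Gaussian, or scaled
Poisson counting noise with a given expected count at unit intensity);
results clip at zero. The noise default is `none`, since the reference
workflow does not quantify the experimental noise level of integrated
intensities.

## Center-of-mass analysis

`com_maps_from_scan()` reduces each measured pixel's detector pattern to the
intensity-weighted centroid shift relative to the nominal peak position:
`comx` is the detector-column (horizontal) shift and `comy` the detector-row
(vertical) shift, signed as measured minus nominal — the axis convention is
pinned here since detector axes are otherwise arbitrary. Zero-intensity
pixels are flagged invalid, not zero. Sparse maps are inpainted
biharmonically, `comx` and `comy` as independent scalar fields, consistent
with the dark-field final images. A median-clip hot-pixel filter
(`filter_hot_pixels()`) is available but off by default for synthetic data.

## Problem sizes and what the checks show

The package's acceptance study — shared by `tests/testthat/test-acceptance.R`
and `scripts/acceptance.R` — uses five seeded 150×100 flake images scanned
to 60% coverage, a geometry small enough to run the whole closed loop in a
few minutes of CPU while keeping flakes and bubbles resolved. On these
images the adaptive scan beats low-discrepancy, uniform-random and raster
masks at matched 10% coverage on both NRMSE and SSIM (uniform random being
worst), its SSIM at 30% coverage is within 5% of its SSIM at 60% (the
stabilization behavior that makes early stopping viable), and its measured
points concentrate within 2 pixels of ground-truth edges far more than
low-discrepancy sampling does. The decision model's ERD ranks unmeasured
pixels in agreement with the measured RD (Spearman rank correlation,
median over the five runs at their 10% states); the evaluation uses the
workflow's own measurement states because those are the states the model
must rank well in practice, and the median over seeds is the same
aggregation its sibling checks use. The center-of-mass study uses five
seeded 64×64 single-bubble stacks with a 24×24 detector: the full-scan
`comx` changes sign across the bubble midline, and maps inpainted from a 20%
adaptive mask reproduce the full-scan maps with lower RMSE than a 20%
uniform-random mask. A scaling probe checks that quadrupling the pixel count
at fixed coverage increases the per-iteration decision time by well under
8×, consistent with the near-linear k-d-tree cost model.

## Known limitations

* The decision engine ranks pixels by *local* expected improvement; fully
  unexplored features smaller than the initial sampling spacing are found
  late (the exploration–exploitation tradeoff). Raising
  `initial_fraction` is the practical mitigation.
* Exact RD under k-NN IDW is intrinsically noisy; rank agreement between
  predicted ERD and exact RD is bounded well below 1 even for an oracle
  regressor on the six features.
* The biharmonic solve factorizes a sparse N×N operator; beyond roughly
  500×500 grids the final inpainting dominates runtime (the in-loop path
  never solves it).
* The simulator's diffraction model is deliberately minimal (isotropic
  Gaussian peaks, gradient-proportional shifts); quantitative strain or
  curvature recovery is out of scope.
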