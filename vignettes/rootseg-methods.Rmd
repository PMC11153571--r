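---
title: "Methods: segmentation, post-processing and biomass quantification in rootseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation, post-processing and biomass quantification in rootseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`rootseg` analyses time series of RGB scans of single root systems grown
in hydroponic imaging chambers. This vignette documents the models and
procedures the package implements, the tunable parameters and their
defaults, the design decisions taken where several reasonable choices
existed, and the limits of what the bundled synthetic data can
demonstrate.

## The segmentation problem

Each scan shows one root system in shades of green and brown on a dark
background, together with class-confusable artifacts: bright droplets
and bubbles, low-contrast condensation fields, and leaf shadows. Labels
distinguish three classes: background (0), noise (1) and root (2).
Two properties dominate the statistics: the heavy class imbalance (over
80% of pixels are background, under 20% root), and the fineness of the
structures of interest (root segments can be a single pixel wide).
Both motivate patch-based training, the sparse-label filter, and
class-weighted training below.

## Patch corpus construction

`extract_patches()` tiles a scan and its label mask into a
non-overlapping grid of `s x s` patches from the top-left origin,
discarding incomplete edge tiles, so an `R x C` image yields
`floor(R/s) * floor(C/s)` patches. Tiling is a partition: overlap would
duplicate training pixels, and padding edge remainders would create
synthetic borders that imitate the background class. Patch provenance
(chamber, timepoint, top-left corner) is recorded so any patch can be
traced to its source pixels.

`filter_sparse_patches()` retains exactly the patches whose fraction of
*annotated* pixels — interpreted as non-background, classes 1 and 2 —
reaches `min_annotated_fraction` (default 0.20). The filter exists to
discard patches that are mostly empty background; counting the noise
class as annotated is deliberate, since artifact-rich regions are
exactly the hard negatives the model must learn. At the default
threshold a 64 px patch needs at least 820 of its 4096 pixels annotated
(819/4096 = 0.19995 falls below the cut).

`split_dataset()` assigns patches uniformly at random to
train/validation/test in 80/10/10 proportions (sizes within one patch of
exact). The default split is at patch level — the simplest reading of a
patch corpus — but `by_chamber = TRUE` assigns whole chambers to one
split, which is the right choice when neighbouring patches of one scan
must not straddle the train/test boundary.

Augmentation (`augment_patch()`) applies, each with an independent coin
flip per draw: rotation (an exact multiple of 90 degrees plus a free
angle in ±45 degrees), horizontal/vertical flips, a 2% random crop
resized back, an integer shift of up to 5% of the side, zoom in
[0.8, 1], and brightness/contrast jitter within ±5% (RGB only). All
geometric transforms are applied identically to the label patch with
nearest-neighbour resampling, so labels never interpolate outside
{0, 1, 2}; resampling uses reflection padding rather than constant
fill, because black corners introduced by zero-padding would imitate the
background class. The warp is implemented in the package so that the
reflection boundary and the paired image/label resampling are exact.

## The residual U-Net

`build_resunet()` constructs a 2-D residual U-Net with (by default)
5 resolution levels and 32 base channels doubling per level
(32-64-128-256-512). Each level, encoder and decoder alike, is one
residual block of two subunits in pre-activation order — batch
normalization, ReLU, 3×3 convolution — with an identity shortcut (a 1×1
projection whenever channels or stride change) and 20% spatial dropout
inside the second subunit during training. Encoder levels 2..5
downsample with stride-2 convolutions; the decoder mirrors them with
nearest-neighbour 2× upsampling followed by a 1×1 channel-halving
convolution, an **additive** skip connection from the same-resolution
encoder level, and a residual block. A final 1×1 convolution yields the
3 class logits. Inputs must have sides divisible by `2^(levels-1)`.

Additive skip fusion (rather than channel concatenation) was an open
design choice. It was adopted because it keeps the decoder in the same
residual idiom as the rest of the network and keeps the decoder lean:
the default configuration has 6 634 601 trainable parameters, whereas
the concatenating variant of the same block layout roughly doubles the
decoder's first-convolution cost (~7.6 M parameters) without a
compensating benefit at the scales this package targets.

Training (`train_resunet()`) minimizes the class-balanced cross-entropy

    L = mean over pixels of  -beta_c * log p_c   at each pixel's true class,

with `beta` the inverse class frequencies of the training labels
normalized to sum to one (`compute_class_weights()`; a class absent from
the corpus is given a one-pixel count with a warning, keeping the
weights finite). Probabilities come from a max-stabilized softmax; the
loss clips probabilities at 1e-12 before the logarithm. The optimizer is
Adam (defaults lr 1e-3, batch 8, both overridable) — the standard choice
for this architecture family; the paper-scale hyper-parameters
(optimizer, schedule, batch) are not prescribed by the design, so they
are plain arguments. Validation loss is tracked every epoch and the
best-validation weights are kept. All randomness — shuffling, dropout,
augmentation draws — derives from the `seed` argument, and two runs with
the same seed produce identical histories.

Full-image inference (`predict_full_image()`) tiles the scan (default
tile 64, overlap 0.25), averages per-class softmax probabilities where
tiles overlap, and argmaxes to the class map. Images smaller than a tile
are reflection-padded and cropped back. Overlap-averaging is the
package's stitching choice: it suppresses tile-boundary seams at the
cost of proportionally more forward passes.

Evaluation (`segmentation_metrics()`) reports accuracy over all three
classes and precision, recall and IOU = TP/(TP+FP+FN) for the root
class, plus the one-vs-rest AUC of the root-class probability (computed
by pROC). When the root class is empty in both truth and prediction,
IOU is defined as 1 and precision/recall are reported as `NA` with a
warning.

## Convex-hull post-processing

Root systems occupy a convex-ish region that only grows over time, while
artifacts scatter over the whole chamber. `rootseg` exploits this by
computing, once per chamber, the convex hull of the **dilated
max-projection** of all timepoints' root predictions (`stack_hull()`;
default dilation radius 2 px, disc structuring element), then cleaning
every timepoint against it (`clean_prediction()`), in this order:

1. take the root class of the per-timepoint map;
2. zero pixels outside the hull;
3. area closing (fill background holes under `area_closing_min`, default 64 px²);
4. area opening (drop foreground components under `area_opening_min`, default 64 px²);
5. final erosion by `erosion_radius` (default 0 = skip).

The area thresholds and dilation radius are free parameters with
sensible desk-scale defaults; nothing in the procedure pins them, so
they are exposed in `morpho_params()`. Erosion comes last so that the
hull and the area filters act on the uneroded prediction.

`graham_scan()` implements the classic scan: the pivot is the
bottom-most point on screen (largest row; leftmost on ties) — a flag
selects the top-most convention instead, and the resulting hull is
identical — remaining points are sorted by polar angle around the pivot
(of points sharing an angle only the farthest survives), and a stack
sweep keeps strictly counterclockwise turns, so collinear points
interior to hull edges are dropped. Sets with fewer than three distinct
points, or entirely collinear sets, return a flagged degenerate hull
(point or segment) rather than an error. The test suite validates the
scan against a brute-force O(n³) maximal-edge construction on over a
thousand random point sets, including duplicate-laden and collinear
ones. `hull_mask()` rasterizes the hull boundary-inclusively by the
half-plane test on every pixel centre.

Mean root thickness is defined as foreground area divided by
medial-skeleton length, with the skeleton computed by Zhang–Suen
thinning (`skeletonize()`): thickness is nowhere defined by the
procedure this package follows, and this estimator is standard,
parameter-free and exactly testable on bars (a 100×5 bar measures
5 ± 0.3 px; dilating it by a disc of radius 2 adds ≈ 4 px).
`optimize_erosion()` grid-searches morphological parameter sets to
minimize the mean absolute error between cleaned-prediction thickness
and ground-truth thickness, pooled over image pairs (pooled rather than
per-image, the simpler objective), breaking ties toward the smaller
erosion radius; it reports per-pair IOU before and after cleaning
alongside the objective.

## Biomass quantification

Image-derived biomass is the root pixel count of the cleaned prediction.
For comparison against destructively measured root weights — available
only at the final acquisition date — counts and weights are L2
normalized across the chambers of that date (`l2_normalize()`), then
related by ordinary least squares (`compare_to_scale()`), reporting
slope, intercept, Pearson r, R² (= r² for simple regression, asserted to
1e-9 in tests) and the residual RMSE on the normalized scale. Because
the regression direction is a convention, the reverse fit is reported
alongside. `growth_table()` emits a tidy (treatment, timepoint, chamber,
biomass) table; chambers whose plants died early simply contribute fewer
rows — missing timepoints are never imputed.

## The phantom generator

`render_phantom()` synthesizes chamber series with exact ground truth:

- **Root growth**: a branching random walk from a fixed seed point near
  the top centre. Every active tip descends exactly one row per step
  with a persistent lateral drift in {-1, 0, 1}; with probability
  `branch_prob` (default 0.3) a tip spawns a branch (capped at 32 tips).
  Strict descent guarantees two structural properties the pipeline
  assumes: the skeleton at timepoint t is a superset of timepoint t-1
  (growth only), and an unbranched walk is a simple 8-connected path.
  The skeleton is dilated by a disc to `root_thickness_px` (default 5)
  and rendered in green-brown hues with per-timepoint blend and
  per-pixel jitter on a near-black background with Gaussian sensor
  noise.
- **Artifacts** (class 1), drawn per timepoint with Poisson count at
  `artifact_density` per megapixel (default 40): droplets as bright
  annuli, bubbles as filled discs, condensation as low-contrast blotch
  fields, shadows as darkened bands; a fraction is placed adjacent to
  the root, and the root is rendered on top.
- **Class balance**: the background fraction of every mask is enforced
  at or above `background_fraction_target` (default 0.8) by truncating
  root growth at a pixel budget and skipping artifacts once the
  foreground budget is spent.

Defaults (512×384 px, 5 timepoints, 80 growth steps per timepoint) were
chosen once as a desk-scale miniature of real chamber scans — roots
reaching ~10–15% of the frame by the final date with artifacts about 1% —
and are not tuned to any test outcome. The generator is deterministic:
one seed, bit-identical scans, masks and manifests.

What the phantoms do **not** emulate: real optics (specular highlights,
chromatic noise, vignetting), root hairs and overlapping root mats,
leaves and shoot structures, condensation that evolves coherently over
time, or annotation error. Consequently, passing tests demonstrate that
the pipeline's machinery is correct and that the patch-size and
class-balance mechanisms behave as designed on separable data; they do
not certify segmentation accuracy on real chamber scans.

## Numerical choices and degenerate inputs

- Loss reduction is the mean over pixels (not the sum), keeping the loss
  scale independent of patch size; probabilities are clipped at 1e-12
  before `log`.
- Batch-norm uses eps 1e-5 and momentum 0.1 running statistics
  (training mode uses batch moments; inference uses running moments).
- Convolution weights are He-initialized from the model seed; building
  a model is itself deterministic.
- Geometric tolerance in hull computations is 1e-9 on cross products;
  hull rasterization is boundary-inclusive.
- Degenerate inputs favour flagged results over exceptions: empty
  filter results warn, empty rasters give thickness 0 with a warning,
  all-zero vectors pass through `l2_normalize()` with a warning,
  degenerate hulls rasterize to their point or segment.
- Raster coordinates are 1-based (row, col) with origin top-left — the
  R convention — while timepoints are 0-based acquisition indices.

## Scale of the built-in study

The acceptance study in the test suite trains patch-64 and patch-256
models on an identical corpus of 20 phantom images (4 chambers × 5
timepoints at 512×384), 6 epochs each at matched learning rate, and
evaluates full-image root IOU on 6 unseen phantom images and biomass
recovery on the 20 training chamber-timepoints. These sizes are the
package's chosen desk-scale study design: large enough for the
patch-size and recovery effects to be unambiguous, small enough to run
routinely on one CPU.

## Known limitations

- The network trains on CPU in R; it is intended for desk-scale models
  and corpora, not for paper-scale training runs (tens of thousands of
  patches), which belong on a GPU framework.
- The convex-hull ROI assumes one root system per chamber whose extent
  grows monotonically; chambers with multiple disconnected plants or
  receding roots violate the model.
- Area opening/closing use connected-component labelling from EBImage;
  component connectivity follows that implementation.
- The thickness estimator is biased on highly branched skeletons
  (junction pixels shorten the skeleton relative to total centreline
  length), which is acceptable for the relative comparisons the erosion
  search makes.
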