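---
title: "Counting dark circular cells: the method behind sccount"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting dark circular cells: the method behind sccount}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Immediate-early-gene markers such as cFos label recently active neurons. In
brightfield immunohistochemistry the positive cells appear as small, dark,
round blobs over a lighter, noisy tissue background, and studies routinely
need counts of them over hundreds of section images. Manual counting is
slow; generic colony counters mis-handle brain tissue. `sccount` implements
a deliberately simple four-step counting scheme plus one learned component
for the single genuinely hard sub-problem: deciding how many cells hide
inside a fused, non-circular blob.

## The pipeline

For an 8-bit grayscale image (intensities 0–255) and a configuration
(`scc_config()`), counting proceeds as:

1. **Threshold.** A pixel is foreground iff its intensity is *strictly
   below* the global threshold (default 115) for dark-on-light staining;
   for fluorescent (light-on-dark) material the comparison is inverted.
   Ties at the threshold are background. No local/adaptive thresholding is
   used: the threshold is a scientific parameter the user sets against
   their staining protocol.

2. **Adaptive opening.** The binary mask is opened (eroded then dilated)
   with a 3×3 square structuring element. Noise speckle grows steeply as
   the threshold approaches the image mean, so the number of
   erosion/dilation passes is driven by the ratio r = threshold / MPI
   (MPI = mean pixel intensity): r < 0.70 → 1, 0.70–0.80 → 2,
   0.80–0.90 → 3, ≥ 0.90 → 4. Only monotonicity of this schedule is
   dictated by the method; the breakpoint table is this package's default
   (chosen to align with the customary threshold-factor working points
   0.7–0.85) and is user-overridable. Pixels outside the image are treated
   as background.

3. **Object selection.** Each 8-connected foreground component becomes one
   contour; interior holes (thin staining can push a few interior pixels
   over the threshold) are filled first. The zeroth-order moment of the
   filled region — its pixel count — is the area; contours with area below
   π·min_radius² (default radius 10 px → 314.16 px²) are discarded.

4. **Circularity and overlap.** Circularity is scored as the negative
   base-10 logarithm of the first Hu invariant η₂₀ + η₀₂ (the sum of
   second-order normalized central moments of the filled region). The score
   is translation-, scale- and rotation-invariant; an ideal disk gives
   −log₁₀(1/2π) ≈ 0.798, and rasterized disks score ≈ 0.79–0.80. Fused
   cell pairs score lower — around or below 0.76, falling further as the
   centres separate. Contours at or above the cutoff (default 0.7) count
   as exactly one cell. The rest are normalized into 64×64 binary patches
   and a small convolutional classifier predicts how many cells (1–4,
   "4" meaning four or more) each contains. The total count is the number
   of circular contours plus the sum of the classifier's predictions — an
   identity asserted on every run.

Watershed splitting is deliberately not used: it can distort cell
morphology, and the classifier answers the only question the count needs
(how many cells), not where their boundaries lie.

### Moment conventions

All moments are computed over pixel centres of the filled region with unit
weight, so the area convention (pixel count) and the π·r² cutoff agree with
each other and with the circularity denominator. Degenerate regions (zero
area or zero second moments) raise errors rather than returning scores.

## The overlap classifier

The classifier is a small convolutional network: fixed 2×2 average pooling
(64→32), 5×5 convolution with 12 filters + ReLU, 2×2 max pool, 3×3
convolution with 24 filters + ReLU, 2×2 max pool, a dense layer of 96
units, and a 4-way softmax. It is trained with Adam (learning rate 1e-3,
halved after 50% and 80% of epochs, minibatch 64, default 35 epochs) on
synthetic patches (`make_overlap_patch()`), 400 per class by default, with
a random square symmetry (one of the 8 flips/rotations) applied to each
training sample. Prediction averages class probabilities over the same 8
symmetries, which is deterministic and stabilizes the hardest distinction
(3 vs 4 lobes). The convolution/backprop machinery is written directly in
vectorized R (im2col + BLAS) and is gradient-checked against numerical
differentiation in the test suite. Training is fully reproducible from its
seed.

Patch normalization (`make_patch()`) crops the filled contour (neighbour
objects masked out), pads by 10% of the larger side, centres it on a square
canvas and resizes to 64×64, re-binarizing at 0.5 — making predictions
exactly translation-invariant and scale-normalized up to resampling.

Training patches are fused clusters of k disks: radii jittered ±30% around
a base radius, each added disk attached to a previously placed one at
centre distance u·(rᵢ+rⱼ)/2 with u ~ U(0.6, 1.6), guaranteeing one
connected component. Two construction guarantees make the labels
well-posed: every disk must keep at least 35% of its area visible (for
pairs this barely constrains the u distribution — two equal disks at
u = 0.6 expose 38% each — but it excludes a small disk swallowed inside a
large one), and for k ≥ 3 the floor rises to 50% so that every cell
contributes a distinct lobe to the silhouette. Without these guarantees a
labelled-3 cluster can present only two lobes and no classifier (nor a
human) could recover the count from the binarized shape.

When no model is supplied the pipeline falls back, with a warning, to a
deterministic area heuristic: round(area / (π·min_radius²·k)) with packing
constant k = 1.5 (fused cells share area), floored at 1. Patches with
fewer than 20 foreground pixels are counted as 1 with a warning. Saved
models carry a format version and loading refuses a mismatch.

## The fabricated-image generator

`fabricate_cfos_image()` emulates validation images with exact ground
truth: n ~ U{5, …, 100} filled circles on a gray background (level 180,
Gaussian noise sd 6, clipped to 0–255 — the background stays ≥ 10 noise
standard deviations above the default threshold, as tissue background does
under a sensible threshold choice). Circle radii are uniform-continuous on
8–15 px, bracketing the default 10 px minimum so the size filter is
genuinely exercised; intensities are drawn from a dark, qualifying range
(60–110) or a light, non-qualifying one (125–175) with equal probability.
Where circles overlap the darker value wins, so a dark cell partially
covered by a light circle keeps its silhouette. Edges are hard
(aliased), as a standard circle rasterizer draws them; `aa = TRUE` enables
coverage-weighted anti-aliasing, but note that blended edges make
near-threshold circles effectively smaller at binarization time and bias
counts low — crisp-edged validation targets are the point of fabricated
images.

Most circles are isolated (and circular by construction); with small
probability a placement is a fused pair (4%) or triple (1%), built with the
same cluster geometry as the training patches so the classifier sees the
geometry it was trained on. Clusters are placed by rejection sampling with
a ≥ 3 px gap between clusters, so distinct clusters never merge and the
ground truth stays exact: `gt_count` is the number of circles that meet the
darkness criterion (on the foreground side of the threshold) *and* the size
criterion (radius ≥ min_radius), each recomputable from the circle table.
Everything is a deterministic function of the seed, byte for byte.

What the generator does *not* simulate: tissue texture, vasculature,
uneven illumination, out-of-focus blur, or intensity gradients within a
cell. Passing the recovery tests therefore demonstrates the pipeline's
correctness on its own model of the data — dark round objects on a
homogeneous noisy background — not performance on real tissue, which
depends on staining quality and threshold choice.

## Evaluation metrics

* `abs_error()` — per-image |reference − method| and its mean.
* `match_detections()` — one-to-one greedy nearest-neighbour matching of
  centroids under a distance tolerance (default 10 px, the minimum cell
  radius; the matching rule between an automated detection and a reference
  mark is a package decision). Pairs are accepted closest-first after a
  global sort with lexicographic tie-breaks, so matching is deterministic
  and order-independent; unmatched detections are false positives,
  unmatched reference points false negatives. Greedy matching can in
  principle differ from optimal assignment when several points crowd
  within one tolerance radius; at realistic cell densities it does not,
  and the tests verify equality with exhaustive optimal matching on
  unambiguous layouts.
* `fit_counts_regression()` — ordinary least squares of method counts on
  reference counts with the usual t-test p-value for the slope. Count
  series are single fits; no multiple-testing correction applies.

## Sweeps

`resize_sweep()` rescales each image to new size = original / factor (so
factor 0.5 *enlarges*) with bilinear interpolation in both directions, and
scales `min_radius` by 1/factor — without that, the size criterion would
not be commensurate across scales and counts could not be compared; the
choice is recorded in the output. Timing columns are informational only:
they depend on hardware. `threshold_sweep()` sets each image's threshold to
factor × its own MPI and reports mean absolute error against a reference.

## Numerical choices and edge cases

* Ties at the threshold → background (strict inequality), documented and
  fixed.
* Pixel coordinates are 0-based, x = column, y = row, origin top-left.
* 16-bit inputs are divided by 257 (min-max stretching is *not* used), so
  absolute thresholds keep their meaning; RGB collapses by 0.299/0.587/0.114
  luminance, rounded.
* Degenerate images (mean intensity 0 or 255) yield a warning and a zero
  count rather than an error, so batches keep running.
* Classifier ties in the softmax argmax resolve to the smaller count.
* Batch processing is sorted by filename; per-image failures warn and are
  skipped.

## Problem sizes in the shipped tests

The test-suite and acceptance computations use 1024×1024 fabricated images
(15 per seed, 3 seeds), a classifier trained on 400 patches per class for
35 epochs, and brute-force oracle comparisons on masks up to 32×32 — sizes
chosen so the whole validation runs comfortably on a single CPU while
leaving the statistics stable: the regression of pipeline counts on ground
truth across the 45 images reproduces a slope within a few hundredths of
one, with classifier held-out accuracy ≈ 0.9–0.95.

## Known limitations

* A single global threshold: images with strong illumination gradients
  need external flat-field correction first.
* The classifier caps cluster counts at "4 or more"; larger aggregates are
  undercounted. At realistic cFos densities such aggregates are rare.
* Contours whose circularity lands between the 0.7 cutoff and the ~0.76
  overlap regime are counted as single cells; a slightly fused pair can
  therefore be undercounted by one. Raising the cutoff trades this against
  sending clean single cells to the classifier.
* No region-of-interest selection: images should be pre-cropped to the
  region of interest.
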