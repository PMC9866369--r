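---
title: "Counting grains in dropping images by density-map regression"
author: "dropcount"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting grains in dropping images by density-map regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The counting model

`dropcount` estimates how many undigested cereal grains appear in an image
of a dairy-cow dropping. Detection-style approaches need a bounding box per
grain, which is impractical for dozens of overlapping, few-pixel objects.
The package instead treats counting as a regression problem on a *density
surface*:

* each annotated grain center (a "dot") contributes one isotropic Gaussian
  kernel `G(x, y) = exp(-((x - x0)^2 + (y - y0)^2) / (2 sigma^2))`;
* the sum of kernels over all dots is the density surface `D(x)`, a
  non-negative function of pixels;
* the integral of `D` over the frame equals the number of dots, and its
  integral over any subregion equals the number of objects in that region
  (`countInRegion()`);
* an encoder–decoder network is trained with per-pixel mean squared error
  to map the image to `D`; at inference the predicted map is summed
  (`countFromDensity()`) to give a real-valued count.

The modelling assumptions are that objects are compact and roughly
uniform in size (so one kernel width fits all), that annotation dots sit
near object centers, and that object appearance is learnable from local
texture — all reasonable for bright grains on fecal background, and all
properties the synthetic generator reproduces.

## Kernel normalization and counting calibration

Two kernel normalizations are supported, because the two natural
conventions conflict:

* `unit_integral` (default): kernel entries sum to 1, so each interior dot
  adds exactly one unit of mass; the count is the plain sum of the map.
* `unit_peak`: the kernel maximum is scaled to exactly 1. Summing such a
  map overcounts by the mass of one kernel, so `countFromDensity()`
  divides by the analytic mass `kernelMass()` of a single truncated
  unit-peak kernel, restoring one-dot-one-count calibration.

Training targets use `unit_integral`; `unit_peak` is retained because
peak-normalized kernels are a common convention for visualized heat maps
and because the calibration-by-division route deserves its own tests.

Numerical choices, all covered by tests:

* **sigma** defaults to 2 px with truncation radius `ceiling(4 * sigma)`.
  Grains at the package's working resolutions span a few pixels; a kernel
  much wider than the object blurs neighbouring grains together, much
  narrower makes the regression target needle-like and hard to fit. The
  truncated tail at 4 sigma carries ~1e-7 of the mass, far below the 1e-6
  count-conservation tolerance.
* **dot snapping**: dots are placed at the nearest integer pixel before
  kernel placement (convolution-of-point-mass semantics); sub-pixel kernel
  placement is out of scope.
* **border handling**: kernels are truncated at the frame border and *not*
  renormalized. A dot within the truncation radius of a border therefore
  contributes slightly less than one count; moving a dot toward a border
  never increases the count (a tested monotonicity property). This is the
  simplest convention and matches how the regression target is actually
  built by frame-limited convolution.
* **ties in max pooling** resolve to the first maximum in memory order,
  fixed by the C++ kernel, so forward passes are bit-reproducible.

## The two architectures

Both families map an `H x W` image to an `H x W` density map through three
downsampling and three upsampling stages (configurable via
`ArchitectureSpec`). Same-padding is used everywhere so the full-frame map
integrates directly to a count; inputs must be divisible by `2^nBlocks`.

* **FCRN variant** (`buildFCRN()`): encoder block *i* stacks *i*
  convolution+ReLU layers, then a 2×2 max-pool; the first block uses the
  5×5 kernel, later blocks 3×3. After the last pool a 1×1 convolution —a
  fully connected layer applied convolutionally— acts as the bottleneck.
  Decoder units are (2×2 stride-2 transposed convolution, ReLU,
  convolution). A final 1×1 convolution maps to one channel.
* **U-Net variant** (`buildUNet()`): encoder blocks of two 3×3
  convolution+ReLU layers and a pool; a two-convolution bridge; decoder
  blocks of a 2×2 up-convolution, concatenation with the same-resolution
  encoder features (skip connection), and two 3×3 convolution+ReLU layers.

Channel schedule: `baseChannels` (default 32) doubling per depth level,
mirrored on the way up — growing feature counts compensate for the spatial
information lost to pooling. Convolution weights use seedable orthogonal
initialization (QR of a Gaussian matrix, gain sqrt(2); gain 1 for the
output head); biases start at zero.

**Output head.** The output activation is *linear* by default, with
negative predicted density clamped to zero at counting time. A terminal
ReLU ("densities must be non-negative by construction") was evaluated and
rejected: with MSE against targets that are zero almost everywhere, the
pre-activation drifts negative over most pixels early in training, the
ReLU then passes no gradient, and the network permanently collapses to the
zero map. `outputActivation = "relu"` remains available in
`ArchitectureSpec` for experimentation, and its non-negativity contract is
tested.

The engine behind both families (same-padded convolution via im2col +
GEMM, 2×2 max pooling, 2×2 stride-2 transposed convolution, with
hand-derived backward passes) is implemented in the package's `src/`; the
analytic gradients are verified against central finite differences in the
test suite, and the fused C++ training pass is verified step-for-step
against a plain R reference walker.

## Training protocol

`TrainConfig` encodes the full protocol; defaults are the study settings:

| parameter | default | meaning |
|---|---|---|
| learningRate | 0.01 | initial SGD step size |
| lrDecayFactor / lrDecayEvery | 10 / 10 | divide lr by 10 every 10 epochs |
| momentum | 0.8 | classical momentum (velocity update `v <- m v + g + wd w`) |
| weightDecay | 0.005 | L2 penalty added to gradients |
| epochs | 200 | training epochs (the protocol is also reported at 100; configurable) |
| batchSize | 1 | minibatch size; 1/8/16 are the compared settings |
| trainFraction | 0.8 | random train share of the split |
| augmentFlips | TRUE | per sample per epoch, one of none/hflip/vflip |
| patchSize | 256 | central square patch fed to the network |
| targetScale | 100 | global factor on density targets |

Loss is the mean over pixels (and batch) of squared error; mean reduction
keeps the learning rate independent of frame size. Flips are applied
*online*, jointly to the image and its density target — the density module
is exactly flip-equivariant, so flipping the target equals rebuilding it
from flipped dots, a tested identity. Each image is standardized to zero
mean and unit standard deviation (`normalizePatch()`; constant patches map
to zeros) before entering the network.

`targetScale` exists because a unit-integral Gaussian with sigma 2 peaks
near 0.04: against inputs of unit variance, raw targets produce poorly
conditioned MSE gradients under the fixed 0.01 learning rate. Scaling
targets by 100 lifts them to order 1; `evaluateNetwork()` and
`runPredict()` divide the scale back out before integrating, so reported
counts are unaffected. The value is a conditioning device chosen once, not
a tuning knob.

All randomness in a run — the split, shuffling, augmentation draws,
initialization — derives from explicit seeds (`TrainConfig@seed`,
`initSeed`), and the RNG state of the caller is never disturbed. Two runs
with identical seeds produce bit-identical loss sequences and parameters;
this is asserted in the tests.

## What the synthetic generator emulates — and what it does not

`generateScene()` emulates the features of farm imagery that matter for
density regression: a mid-gray textured background (coarse smooth noise),
illumination varying linearly across the frame with random direction and
strength, 8-bit quantization on export, additive pixel noise, and bright
elliptical grain-like blobs of random size, orientation and overlap, with
*exact* center labels. Background, grain and noise streams are seeded
independently, so the same scene can be regenerated with and without its
grains — which is how the tests verify that blob centers are strictly
brighter than the grain-free background.

It does not attempt photorealistic fecal texture, camera optics (blur,
vignetting, perspective), moisture glare, or grain-on-grain occlusion
beyond simple additive overlap. Consequently, passing tests demonstrate
that the pipeline is *correct* (targets well-calibrated, gradients exact,
training descends, counts recovered on held-out scenes) — not that any
fixed accuracy carries over to real farm images, whose difficulty depends
on the camera and conditions.

Generator defaults are 256×256 frames with 5–60 grains of semi-axes 2–5 px
(the real-data count range is not documented anywhere, so the range is a
field-plausible choice kept configurable); the scaled-down experiment used
by the tests and `scripts/acceptance.R` works at 64×64 with 5–15 grains of
semi-axes 1.5–3 px, preserving object-to-frame proportions.

## Design choices where the protocol was open

* **Annotation format**: CSV `row,col` coordinate lists are canonical
  (lossless, diffable); red-dot marker images are an import path via
  8-connected component centroids. Coordinates are 0-based (row, col)
  reals, row increasing downward.
* **FCRN block count**: descriptions of this architecture oscillate
  between three pooling stages and a "fourth Conv unit"; both cannot hold
  at once. Three blocks plus the 1×1 bottleneck standing in for the fourth
  unit preserves the symmetric three-down/three-up layout that shape
  preservation requires.
* **Kernel-size placement** ("3×3 and 5×5"): 5×5 in the first FCRN block
  where the receptive field matters most, 3×3 elsewhere; the U-Net uses
  3×3 throughout per its own description.
* **Split granularity**: a simple random 80/20 split over images;
  stratification (e.g. by farm) is not modeled because the synthetic data
  has no such grouping.
* **Predicted counts are not rounded**: MAE/RMSE operate on raw real
  predictions, preserving calibration information.
* **Epochs**: the protocol is stated at 200 epochs in one place and 100 in
  another; 200 is the default, and every experiment in this package states
  its own (smaller) epoch count explicitly.
* **Comparison harness controls**: `runComparison()` reuses one split and
  one initialization seed across all (family, batch size) cells so the
  cell effect is isolated.

## Problem sizes used in tests and the acceptance script

The end-to-end experiment trains at 64×64 with base width 16 for 30 epochs
on 240 scenes (batch 8) and evaluates on 60 held-out scenes — chosen as the
smallest setting at which both families clearly separate from the
all-zeros baseline (MAE ≈ 2 vs ≈ 10) while a full run stays in the minutes
range on a single core. Unit tests use 16–64 px frames and 2–4 channel
networks. The deeper numerical checks (oracle equivalence of density
construction, gradient checks, fused-vs-reference engine equality) run at
tiny sizes where brute force is exact and cheap.

## Known limitations

* Training is CPU-bound and single-threaded beyond BLAS; the package is
  sized for method study, not production-scale training.
* One global sigma: no perspective-adaptive or k-nearest-neighbor kernel
  widths; scenes with strong scale variation would need them.
* Counts near frame borders are slightly underestimated by construction
  (truncated kernels); with the default margin and sigma the bias is well
  under one grain per image.
* The checkpoint format is R serialization (RDS), bit-exact across
  save/load but not interoperable with other frameworks; density maps
  export to NPY for interchange instead.
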