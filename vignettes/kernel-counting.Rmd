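---
title: "Counting corn kernels with a sliding-window CNN pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting corn kernels with a sliding-window CNN pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(maizecount)
```

## The problem and the model

Estimating grain yield in season requires the number of kernels per ear,
and counting them by hand is slow and error-prone. The detection problem is
unusual among object-detection tasks: a single ear image contains several
hundred instances of one object class, the instances nearly touch, and the
images are taken at arbitrary angles over arbitrary backgrounds. Modern
anchor-based detectors are data-hungry; with only a small hand-labelled
patch dataset available, a sliding-window design is the pragmatic choice.

`maizecount` composes four stages:

1. **Window scoring.** A 32×22 window (height × width — kernels are taller
   than wide) is slid over the image at a configurable stride. Each crop is
   bilinearly rescaled to the 32×32 classifier input and scored by a CNN
   with a sigmoid confidence head. The architecture (two 3×3/32
   convolutions, 2×2/s2 average pool, three 3×3/64 convolutions, 7×7/s1
   average pool, FC-256, FC-128, FC-1; batch normalization + ReLU after
   every layer except the head; all convolutions unpadded, stride 1) gives
   activation shapes 30×30×32 → 28×28×32 → 14×14×32 → 12×12×64 → 10×10×64 →
   8×8×64 → 2×2×64 → 256 → 128 → 1.
2. **Greedy NMS.** Boxes with confidence ≥ 0.5 are pruned by repeatedly
   keeping the highest-confidence box and deleting every remaining box with
   IOU strictly greater than λ. "Strictly greater" matters at the margin: a
   pair at exactly λ survives.
3. **Center regression.** A second CNN (max pooling instead of average,
   FC-100/50/10/2, no batch norm, no dropout) maps each kept 32×32 patch to
   the kernel center. Boxes drawn over a dense ear would overlap
   illegibly — and crowded or angled kernels are not centered in their
   windows — so the pipeline reports center points rather than boxes.
4. **Extrapolation.** The whole-ear estimate is
   `round(factor × n_detected)` with `factor = 2.5` by default: a 180°
   photograph shows half the ear, and about two kernel columns on each
   silhouette edge are too foreshortened to detect, so the visible fraction
   is modelled as 40% of the ear's columns.

## Training protocols and the parameters that matter

The classifier trains with Adam on the binary log loss: mini-batch 128,
25,000 iterations, Xavier-initialized weights, learning rate 3·10⁻⁴
("0.03%") reduced once to 1·10⁻⁴ ("0.01%") when the test loss plateaus.
The regressor trains with Adam on the smooth-L1 loss (quadratic inside one
unit of residual, linear outside — robust to labelling outliers):
mini-batch 45, 25,000 iterations, learning rate 3·10⁻⁴. These are the
package defaults in `classifier_config()` / `regressor_config()`;
desk-scale experiments override the iteration counts (see below).

Decisions the protocol leaves open, and what this package does:

* *Plateau rule.* "Reduce when the error plateaus" is implemented as: no
  test-loss improvement greater than 10⁻⁴ over 5 consecutive evaluations,
  evaluating every 100 iterations. All three numbers are configurable.
* *Optimizer wording.* Both "stochastic gradient descent" and "Adam" are
  commonly named in such protocols; here mini-batch stochastic sampling is
  combined with Adam as the update rule.
* *Regression targets.* The network predicts centers in normalized patch
  units [0,1]², rescaled to pixels at the interface; O(1) targets keep the
  optimization well-conditioned and the linear FC-2 head is agnostic to the
  choice. Predictions are clamped into the patch rather than rejected, so a
  hard side-of-ear kernel degrades gracefully.
* *Decision threshold.* Confidence ≥ 0.5 converts the sigmoid output into a
  class label, both for metrics and for detection.
* *Batch-norm details.* Momentum 0.9, ε = 10⁻⁵, biased batch variance,
  running statistics at inference. At inference the per-channel affine is
  folded into the preceding convolution/FC weights — a pure algebraic
  rewrite that roughly halves scoring cost.
* *Sliding stride.* Never part of the protocol; default (4, 4) px, far
  below the kernel size, so every kernel is covered by several windows and
  NMS removes the redundancy. The recovery study uses (8, 8) to bound run
  time; at kernel radii of 10–12 px this still covers each kernel with
  multiple windows.
* *λ (NMS overlap).* Default 0.3, exposed as a flag because counts are
  sensitive to it: too low merges neighbouring kernels, too high lets
  duplicate windows of one kernel survive.
* *HOG baseline.* 4×4-pixel cells, 2×2-cell blocks, 9 unsigned orientation
  bins, 1-cell block stride (descriptor length 1764 for a 32×32 patch),
  linear SVM with cost 1. The descriptor is computed in-package (no HOG
  implementation exists in the installed R stack); the SVM is `e1071`.

## Patch datasets

The labeling rule is total: a crop containing exactly one kernel center is
a positive; zero or two-plus centers make it a negative; crops with exactly
one center are rejected when sampling negatives. Centers are counted with
the half-open convention `[x0, x0+w) × [y0, y0+h)`. Positive crops take the
annotated kernel box dilated by 2 px (hand-cropping produces similar scale
variation); "augment around 70% of the training data" is implemented as
exactly `round(0.7 n)` patches picked without replacement, each receiving
one flipped/color-jittered copy — which makes the bookkeeping reproducible:
16,391 patches split 80/20 give 3,278 test patches; 6,978 kernel patches
give 1,396/5,582; 13,113 training patches augment to 22,292. Splits use
unstratified uniform sampling (stratification is not part of the protocol)
and base R's round-half-to-even only ever meets non-half fractions in these
sizes. Color jitter is ±20% brightness and saturation and ±10° hue;
flip transforms move stored centers through `x' = 32 − x` (consistent with
treating pixel `i` as the interval `[i, i+1)`).

## The synthetic generator: what it emulates and what it does not

No annotated ear-image dataset is publicly deposited, so the package
generates its own study data. `render_ear_image()` builds an ear as a
staggered lattice of shaded elliptical kernels (hue-jittered around kernel
yellow, radial shading plus an off-center highlight) inside a rounded
silhouette, over value-noise backgrounds tinted as soil, grass, hand, or
plain gray; global lighting gain varies per scene, the ear tilts in the
image plane, and kernel positions get clipped Gaussian jitter.

Three generator choices are deliberate design decisions rather than
emulation:

* *Uniform column spacing, curvature in appearance only.* Kernels near the
  silhouette edges are horizontally compressed and darkened (the visual
  effect of cylinder curvature), but the lattice spacing stays uniform at
  2.2 r horizontally (alternate columns offset by half a row of 2.4 × 1.3 r).
  This keeps two invariants that matter downstream: the minimum pairwise
  center distance never falls below the kernel radius, and every kernel
  admits at least one 32×22 window containing its center and no other — so
  a perfect classifier implies perfect recall. On a real ear the
  edge-column spacing itself compresses, which is one reason real recall
  is harder than synthetic recall.
* *The visible face is exactly 40% of the ear.* The whole-ear ground truth
  is `round(2.5 × visible_columns) × rows`. This builds the symmetric-ear
  premise into the data, so the count-accuracy experiment tests the
  pipeline's detection quality, not the premise itself. On real ears the
  2.5 factor is itself an approximation with ear-to-ear variance.
* *Per-ear sampling.* Radius, tilt, column and row counts are drawn once
  per ear; rows per column is a single draw (a degenerate range like
  `c(30, 30)` with 14 columns yields exactly 420 kernels, which the tests
  exploit).

Passing the synthetic recovery study therefore shows that the
implementation — training loop, scoring, NMS, regression, extrapolation —
is internally correct and convergent. It does not show field readiness:
the generator has no occlusion by husks, no specular glare, no damaged or
irregular kernels, no out-of-plane perspective, and its backgrounds are
statistically simple. Scene dimensions default to 768-wide full-ear
photographs (1024×768).

## Desk-scale problem sizes

`kernel_recovery_study()` fixes the package's evaluation experiment: 6
training scenes and 10 evaluation scenes of 1024×544 px (11–13 visible
columns × 18–24 kernels, radius 10–12 px, tilt ±10°, random backgrounds),
about 4,200 patches after augmentation, classifier batch 48 for 400
iterations, regressor batch 45 for 450 iterations, detection at stride 8
with λ = 0.3 and confidence 0.5. Pilot runs showed both losses flatten
well before these iteration counts on the separable synthetic data (test
log loss < 0.01 by iteration 200), so the full 25,000-iteration protocol
is unnecessary at this scale. Detections are matched one-to-one to ground
truth within half a column spacing (~11 px); the study reports recall,
false-positive rate, count RMSE/MAE/correlation, scenes within ±15% of
truth, and held-out center error in pixels.

## Numerical and engineering notes

* Convolutions are im2col GEMMs in RcppArmadillo; activations for a batch
  are `(H·W·C) × N` matrices in R array layout, so a patch enters the
  network as `as.vector()` of its `[32, 32, 3]` array with no copying
  logic in between.
* All randomness flows through R's RNG; `with_seed()` isolates and
  restores RNG state, and one master seed expands into per-stage seeds.
  Identical seeds reproduce scenes, crop origins, loss histories, and
  counts bit for bit on the same platform.
* NMS ties on confidence break by smaller `(y, x)` origin and then input
  index, making the kept set independent of input order.
* `extrapolate_total()` rounds half away from zero (252.5 → 253). How the
  original extrapolation handled non-integer products is unrecoverable
  from printed counts, so the rule here is a documented package decision.
* The IOU uses continuous half-open boxes; degenerate (zero-area) boxes
  are rejected as errors rather than treated as IOU 0.

## Known limitations

* Synthetic-to-real transfer is untested by construction: no real
  annotated ears are available to the package.
* The sliding-window design rescans overlapping content; scoring a
  1024×544 scene at stride 8 evaluates ~8,000 windows. Batched scoring and
  BN folding keep this to tens of seconds on one CPU, but the method is
  inherently slower than single-pass detectors.
* Counting by `2.5 × one side` inherits the symmetric-ear assumption;
  irregular ears (disease, drought tip-back) violate it. The factor is a
  parameter precisely because of this.
* The regressor is only applied to post-NMS kernel windows, so center
  quality cannot rescue windows the classifier missed.
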