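# maizecount

Image-based detection and counting of corn (*Zea mays*) kernels while they
are still on the ear. Counting kernels in the field is the bottleneck of
many yield-estimation workflows: a well-developed ear carries 650–800
kernels, they nearly touch each other, and photographs are taken at odd
angles under uncontrolled lighting over soil, grass, or a hand. `maizecount`
implements a sliding-window detection pipeline for exactly this regime, in R
with a small compiled (RcppArmadillo) numerical core and no deep-learning
framework dependency.

## The method

For an ear image `I` and a window of size 32×22 px scanned at stride
`(s_y, s_x)`:

1. **Patch classification.** Every window crop is rescaled to 32×32 and
   scored by a convolutional network — conv3×3(32)×2, avgpool2×2/s2,
   conv3×3(64)×3, avgpool7×7/s1, FC-256, FC-128, FC-1 — with batch
   normalization and ReLU after every layer and a sigmoid head, giving a
   confidence `p ∈ [0,1]` that the window holds exactly one kernel. The
   network is trained with Adam on the log loss (mini-batches without
   replacement, Xavier initialization, learning rate 3·10⁻⁴ dropped to
   1·10⁻⁴ when the test loss plateaus). A HOG (4×4 cells, 2×2 blocks, 9
   bins) + linear SVM baseline is included for comparison.
2. **Non-maximum suppression.** Windows with `p ≥ 0.5` enter greedy NMS:
   repeatedly keep the highest-confidence box and delete every remaining box
   whose IOU with it exceeds λ (default 0.3). IOU is computed on half-open
   boxes `[x, x+w) × [y, y+h)`.
3. **Center regression.** Each kept window is passed to a second network
   (conv3×3(32)×2, maxpool2×2, conv3×3(64)×3, maxpool2×2, FC-100/50/10/2,
   ReLU everywhere but the linear output) that regresses the kernel center
   `(x, y)` inside the patch, trained with the smooth-L1 loss
   `f(d) = 0.5 d²` for `|d| < 1`, `|d| − 0.5` otherwise.
4. **Count extrapolation.** A 180° photograph shows one side of the ear,
   and the extreme left/right kernel columns are too foreshortened to
   detect — roughly 40% of the ear's columns are countable. The whole-ear
   estimate is therefore `total = round(2.5 × n_detected)` (half away from
   zero; the factor is configurable).

Counting accuracy is scored with RMSE, MAE, and the Pearson correlation
between estimated and true counts.

Because no public annotated kernel dataset exists, the package ships a
procedural generator of annotated ear scenes ([`render_ear_image()`],
[`render_batch_scene()`]): shaded elliptical kernels on a staggered lattice
inside an ear silhouette, foreshortened and darkened toward the edges, over
soil/grass/hand/plain value-noise backgrounds, with exact sub-pixel center
annotations. Every stage of the pipeline is trained and evaluated against
this generator.

## Worked example

```r
library(maizecount)

# 1. a synthetic annotated scene
params <- ear_scene_params(image_size = c(1024, 544), rng_seed = 42)
img <- render_ear_image(params)
img
#> Annotated image: 1024 x 544 px, 198 kernel center(s), 1 ear(s), whole-ear ground truth 504

# 2. patch datasets from a few training scenes
pos <- extract_positive_patches(img, margin = 2)
neg <- extract_negative_patches(img, n = 180, rng_seed = 42)
patches <- augment_patches(c(pos, neg), fraction = 0.7, rng_seed = 1)
split <- split_dataset(patch_dataset(patches), test_fraction = 0.2, rng_seed = 2)

# 3. train both networks (desk-scale iteration counts)
clf <- train_classifier(split$train, split$test,
                        classifier_config(batch_size = 48, total_iterations = 400))
reg <- train_regressor(patch_dataset(pos), config =
                       regressor_config(total_iterations = 450))

# 4. count kernels on a new scene
scene <- render_ear_image(ear_scene_params(image_size = c(1024, 544), rng_seed = 7))
est <- count_kernels(scene, clf, reg, nms_config(stride = c(8, 8)), factor = 2.5)
est
#> Kernel count: 309 detected on the visible side x 2.50 -> 773 total
scene$total_kernels
#> [1] 768
```

The printed estimate means: 309 post-NMS windows were classified as
kernels on the camera-facing side (the scene renders 312 visible kernels),
and the symmetric-ear factor turns them into a whole-ear estimate of 773
against a ground truth of 768 — a +0.7% error on this seed; across seeds
the estimate typically lands within a few percent (see
`kernel_recovery_study()`). `est$centers` holds one regressed sub-pixel center
per detection; `render_overlay()` writes the boxes/dots onto a copy of the
image.

`kernel_recovery_study()` packages this whole experiment (6 training
scenes, 10 evaluation scenes, ~4,200 patches) and reports detection recall,
false-positive rate, per-scene count errors, and the held-out
center-regression error.

A thin command-line wrapper is installed as `exec/maizecount`
(`generate`, `make-patches`, `train-classifier`, `train-regressor`,
`detect`, `count`, `evaluate`); run it without arguments for usage.

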