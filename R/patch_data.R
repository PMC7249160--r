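# Construction, labeling, augmentation and splitting of the 32x32 patch
# datasets that train the kernel classifier and the center regressor.
#
# Labeling rule (total over candidate crops): a crop containing exactly one
# kernel center is a positive; a crop containing zero or two-plus centers is a
# negative; crops with exactly one center are rejected when sampling
# negatives. Centers are counted with the half-open convention
# x in [x0, x0 + w), y in [y0, y0 + h).

PATCH_SIZE <- 32L

#' A labelled 32x32 training patch
#'
#' @param pixels `32 x 32 x 3` integer array (8-bit channels).
#' @param label `"kernel"` or `"non_kernel"`.
#' @param center For kernel patches, the in-patch kernel center `(x, y)`,
#'   continuous, each coordinate in `[0, 32)`. Must be `NULL` for
#'   non-kernel patches.
#' @param source Optional provenance: source image id and crop origin/size.
#'
#' @return An object of class `kernel_patch`.
#' @export
patch <- function(pixels, label = c("kernel", "non_kernel"), center = NULL,
                  source = NULL) {
  label <- match.arg(label)
  d <- dim(pixels)
  if (length(d) != 3L || d[1] != PATCH_SIZE || d[2] != PATCH_SIZE || d[3] != 3L) {
    stop("`pixels` must be a 32 x 32 x 3 array", call. = FALSE)
  }
  if (!is.null(center)) {
    if (label != "kernel") {
      stop("only kernel patches carry a center", call. = FALSE)
    }
    center <- as.numeric(center)
    if (length(center) != 2L || any(center < 0) || any(center >= PATCH_SIZE)) {
      stop("`center` must be (x, y) with each coordinate in [0, 32)",
           call. = FALSE)
    }
  }
  structure(list(pixels = clamp_u8(pixels), label = label, center = center,
                 source = source),
            class = "kernel_patch")
}

#' @export
print.kernel_patch <- function(x, ...) {
  cat(sprintf("32x32 patch, label: %s", x$label))
  if (!is.null(x$center)) {
    cat(sprintf(", center (%.2f, %.2f)", x$center[1], x$center[2]))
  }
  cat("\n")
  invisible(x)
}

#' A labelled patch dataset
#'
#' @param patches List of [patch()] objects.
#' @param rng_seed Seed recorded for provenance.
#'
#' @return An object of class `patch_dataset`; `length()` gives the number of
#'   patches and `summary()` the class counts.
#' @export
patch_dataset <- function(patches, rng_seed = NA_integer_) {
  stopifnot(is.list(patches))
  ok <- vapply(patches, inherits, logical(1), "kernel_patch")
  if (!all(ok)) stop("all elements must be `kernel_patch` objects", call. = FALSE)
  structure(list(patches = patches, rng_seed = rng_seed),
            class = "patch_dataset")
}

#' @export
length.patch_dataset <- function(x) length(x$patches)

#' @export
print.patch_dataset <- function(x, ...) {
  tab <- patch_label_counts(x)
  cat(sprintf("Patch dataset: %d patches (%d kernel, %d non_kernel)\n",
              length(x), tab[["kernel"]], tab[["non_kernel"]]))
  invisible(x)
}

#' @export
summary.patch_dataset <- function(object, ...) {
  counts <- patch_label_counts(object)
  structure(list(n = length(object), counts = counts), class = "summary.patch_dataset")
}

#' @export
print.summary.patch_dataset <- function(x, ...) {
  cat(sprintf("%d patches: %d kernel, %d non_kernel\n",
              x$n, x$counts[["kernel"]], x$counts[["non_kernel"]]))
  invisible(x)
}

#' Class counts of a patch dataset
#' @param dataset A [patch_dataset()].
#' @return Named integer vector with `kernel` and `non_kernel` counts.
#' @export
patch_label_counts <- function(dataset) {
  labs <- vapply(dataset$patches, `[[`, character(1), "label")
  c(kernel = sum(labs == "kernel"), non_kernel = sum(labs == "non_kernel"))
}

# number of annotated centers falling in the half-open window
centers_in_window <- function(centers, x0, y0, w, h) {
  if (is.null(centers) || nrow(centers) == 0L) return(integer(0))
  which(centers[, 1] >= x0 & centers[, 1] < x0 + w &
        centers[, 2] >= y0 & centers[, 2] < y0 + h)
}

# Crop (integer-aligned, shifted inside bounds) and rescale to 32x32,
# mapping `point` through the same transform. Returns NULL if infeasible.
crop_to_patch <- function(pixels, x, y, w, h, point = NULL) {
  cw <- crop_window(pixels, x, y, w, h)
  if (is.null(cw)) return(NULL)
  out <- bilinear_resize(cw$pixels, PATCH_SIZE, PATCH_SIZE)
  res <- list(pixels = clamp_u8(out), x = cw$x, y = cw$y, w = cw$w, h = cw$h)
  if (!is.null(point)) {
    res$point <- c((point[1] - cw$x) * PATCH_SIZE / cw$w,
                   (point[2] - cw$y) * PATCH_SIZE / cw$h)
  }
  res
}

#' Extract positive (single-kernel) patches from an annotated image
#'
#' For each ground-truth kernel, the crop window is its box dilated by
#' `margin` px on every side. The crop is kept only when it contains exactly
#' that kernel's center and no other -- a crop showing two or more kernels is
#' never a positive sample. Kept crops are rescaled to 32x32 and the center is
#' carried through the same transform into patch coordinates.
#'
#' @param image An [annotated_image()] with at least one center and boxes.
#' @param margin Dilation of the ground-truth box in pixels.
#'
#' @return List of kernel-labelled [patch()] objects (possibly shorter than
#'   the number of centers: crowded kernels whose window captures a second
#'   center are skipped, not errors).
#' @export
extract_positive_patches <- function(image, margin = 2) {
  stopifnot(inherits(image, "annotated_image"))
  if (is.null(image$centers) || nrow(image$centers) == 0L) {
    stop("`image` has no annotated centers", call. = FALSE)
  }
  if (is.null(image$boxes)) {
    stop("`image` must carry per-kernel boxes to cut positives", call. = FALSE)
  }
  out <- vector("list", nrow(image$centers))
  kept <- 0L
  for (i in seq_len(nrow(image$centers))) {
    b <- image$boxes[i, ]
    x0 <- floor(b[1] - margin); y0 <- floor(b[2] - margin)
    w <- ceiling(b[3] + 2 * margin); h <- ceiling(b[4] + 2 * margin)
    res <- crop_to_patch(image$pixels, x0, y0, w, h, point = image$centers[i, ])
    if (is.null(res)) next
    hits <- centers_in_window(image$centers, res$x, res$y, res$w, res$h)
    if (length(hits) != 1L || hits != i) next
    kept <- kept + 1L
    out[[kept]] <- patch(res$pixels, "kernel",
                         center = pmin(res$point, PATCH_SIZE - 1e-9),
                         source = list(kernel = i, x = res$x, y = res$y,
                                       w = res$w, h = res$h))
  }
  out[seq_len(kept)]
}

#' Sample negative (non-kernel) patches from an annotated image
#'
#' Draws random crops at random positions and keeps those containing zero
#' centers or two-plus centers; a crop containing exactly one center is
#' rejected and resampled. Crop sizes follow the image's kernel-box scale
#' (or 24 px on an unannotated image) so negatives match positives in scale.
#'
#' @param image An [annotated_image()].
#' @param n Number of negatives to sample.
#' @param rng_seed Seed; a fixed seed reproduces crop origins exactly.
#' @param max_draws Sampling budget before giving up.
#'
#' @return List of `n` non-kernel [patch()] objects.
#' @export
extract_negative_patches <- function(image, n, rng_seed = 1L,
                                     max_draws = 100L * n) {
  stopifnot(inherits(image, "annotated_image"))
  stopifnot_scalar(n, "n", lower = 1)
  n <- as.integer(n)
  H <- dim(image$pixels)[1]; W <- dim(image$pixels)[2]
  base <- if (!is.null(image$boxes) && nrow(image$boxes) > 0) {
    stats::median(pmax(image$boxes[, 3], image$boxes[, 4]))
  } else 24
  with_seed(rng_seed, {
    out <- vector("list", n)
    kept <- 0L; draws <- 0L
    while (kept < n && draws < max_draws) {
      draws <- draws + 1L
      size <- round(base * runif(1, 0.8, 1.6))
      size <- max(8L, min(as.integer(size), min(H, W)))
      x0 <- sample.int(W - size + 1L, 1L) - 1L
      y0 <- sample.int(H - size + 1L, 1L) - 1L
      hits <- centers_in_window(image$centers, x0, y0, size, size)
      if (length(hits) == 1L) next   # single full kernel: not a negative
      res <- crop_to_patch(image$pixels, x0, y0, size, size)
      kept <- kept + 1L
      out[[kept]] <- patch(res$pixels, "non_kernel",
                           source = list(x = res$x, y = res$y, w = size,
                                         h = size, n_centers = length(hits)))
    }
    if (kept < n) {
      stop(sprintf("found only %d qualifying crops in %d draws", kept, draws),
           call. = FALSE)
    }
    out
  })
}

# flip a patch's pixels and (optionally) its center; x' = 32 - x under a
# left-right flip with the half-open pixel convention.
flip_patch <- function(px, center, flip_h, flip_v) {
  if (flip_h) {
    px <- px[, PATCH_SIZE:1, , drop = FALSE]
    if (!is.null(center)) center[1] <- PATCH_SIZE - center[1]
  }
  if (flip_v) {
    px <- px[PATCH_SIZE:1, , , drop = FALSE]
    if (!is.null(center)) center[2] <- PATCH_SIZE - center[2]
  }
  if (!is.null(center)) center <- pmin(center, PATCH_SIZE - 1e-9)
  list(pixels = px, center = center)
}

#' Augment a fraction of patches with flips and color jitter
#'
#' Selects `round(fraction * length(patches))` patches without replacement
#' and appends exactly one augmented copy of each: an independent random
#' horizontal and/or vertical flip plus color jitter (brightness and
#' saturation scaled by up to +/-20%, hue rotated by up to +/-10 degrees).
#' Originals are retained and labels never change; kernel centers are
#' transformed consistently with the flip.
#'
#' @param patches List of [patch()] objects.
#' @param fraction Proportion of patches to augment, in `[0, 1]`.
#' @param rng_seed Seed for the selection and the augmentation draws.
#'
#' @return List of patches: the originals followed by the augmented copies.
#' @export
augment_patches <- function(patches, fraction = 0.7, rng_seed = 1L) {
  stopifnot_scalar(fraction, "fraction", lower = 0, upper = 1)
  n <- length(patches)
  n_aug <- round(fraction * n)
  if (n_aug == 0) return(patches)
  with_seed(rng_seed, {
    idx <- sample.int(n, n_aug)
    copies <- vector("list", n_aug)
    for (k in seq_len(n_aug)) {
      p <- patches[[idx[k]]]
      flip_h <- runif(1) < 0.5
      flip_v <- runif(1) < 0.5
      fl <- flip_patch(p$pixels, p$center, flip_h, flip_v)
      px <- jitter_colors(fl$pixels,
                          brightness = runif(1, 0.8, 1.2),
                          saturation = runif(1, 0.8, 1.2),
                          hue_shift = runif(1, -10, 10))
      copies[[k]] <- patch(px, p$label, center = fl$center,
                           source = c(p$source, list(augmented_from = idx[k])))
    }
    c(patches, copies)
  })
}

#' Split a patch dataset into train and test partitions
#'
#' Uniform unstratified sampling without replacement; the test partition gets
#' `round(test_fraction * n)` patches (round half to even, as in base R) and
#' the split is reproduced exactly by the seed.
#'
#' @param dataset A [patch_dataset()].
#' @param test_fraction Proportion held out, strictly between 0 and 1.
#' @param rng_seed Seed determining membership.
#'
#' @return List with `train` and `test` [patch_dataset()]s (disjoint, union =
#'   input).
#' @export
split_dataset <- function(dataset, test_fraction = 0.2, rng_seed = 1L) {
  stopifnot(inherits(dataset, "patch_dataset"))
  if (!is.numeric(test_fraction) || length(test_fraction) != 1L ||
      test_fraction <= 0 || test_fraction >= 1) {
    stop("`test_fraction` must be strictly between 0 and 1", call. = FALSE)
  }
  n <- length(dataset)
  n_test <- as.integer(round(test_fraction * n))
  if (n_test == 0L || n_test == n) {
    stop("split would leave an empty train or test partition", call. = FALSE)
  }
  with_seed(rng_seed, {
    test_idx <- sort(sample.int(n, n_test))
    list(train = patch_dataset(dataset$patches[-test_idx], rng_seed = rng_seed),
         test = patch_dataset(dataset$patches[test_idx], rng_seed = rng_seed))
  })
}

# Flatten a dataset (or list of patches) into the matrix form the network
# consumes: X is 3072 x N in [0, 1], y is 0/1 (kernel = 1), centers is 2 x N
# (NA where absent).
patches_to_matrix <- function(patches) {
  if (inherits(patches, "patch_dataset")) patches <- patches$patches
  n <- length(patches)
  X <- matrix(0, PATCH_SIZE * PATCH_SIZE * 3L, n)
  y <- numeric(n)
  centers <- matrix(NA_real_, 2L, n)
  for (i in seq_len(n)) {
    p <- patches[[i]]
    X[, i] <- as.numeric(p$pixels) / 255
    y[i] <- as.numeric(p$label == "kernel")
    if (!is.null(p$center)) centers[, i] <- p$center
  }
  list(X = X, y = y, centers = centers)
}
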