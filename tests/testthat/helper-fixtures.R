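# Shared fixtures, built in code and memoised across test files. The "toy"
# patch sets are trivially color-separable (pure yellow kernels vs
# green/gray/brown non-kernels) so short training runs reach perfect
# held-out accuracy; the "small scene" fixtures are full synthetic ears at
# reduced size.

fixture_env <- new.env(parent = emptyenv())

memo_fixture <- function(name, expr) {
  if (!exists(name, envir = fixture_env, inherits = FALSE)) {
    assign(name, force(expr), envir = fixture_env)
  }
  get(name, envir = fixture_env)
}

# 32x32 toy patch with small deterministic texture noise. Kernel patches get
# a filled yellow ellipse on a dark backdrop (separable by both color and
# shape, so the gradient-based HOG baseline can solve the toy problem too);
# non-kernel patches are flat background colors.
toy_color_patch <- function(rgb, label, seed) {
  px <- maizecount:::with_seed(seed, {
    arr <- array(0, c(32, 32, 3))
    for (c in 1:3) {
      arr[, , c] <- pmin(pmax(rgb[c] + round(rnorm(1024, 0, 6)), 0), 255)
    }
    if (label == "kernel") {
      yy <- matrix(1:32, 32, 32); xx <- t(yy)
      inside <- ((xx - 16.5) / 9)^2 + ((yy - 16.5) / 12)^2 <= 1
      kernel_col <- c(230, 190, 60)
      for (c in 1:3) {
        ch <- arr[, , c]
        ch[inside] <- pmin(pmax(kernel_col[c] + round(rnorm(sum(inside), 0, 6)),
                                0), 255)
        arr[, , c] <- ch
      }
    }
    arr
  })
  center <- if (label == "kernel") c(16, 16)
  patch(px, label, center = center)
}

toy_patchset <- function(n_pos = 100, n_neg = 100, seed = 1) {
  neg_cols <- list(c(70, 112, 48), c(128, 128, 128), c(118, 86, 54))
  pos <- lapply(seq_len(n_pos), function(i) {
    toy_color_patch(c(80, 55, 40), "kernel", seed * 1000 + i)  # dark backdrop
  })
  neg <- lapply(seq_len(n_neg), function(i) {
    toy_color_patch(neg_cols[[1 + i %% 3]], "non_kernel", seed * 2000 + i)
  })
  patch_dataset(c(pos, neg), rng_seed = seed)
}

toy_split <- function() {
  memo_fixture("toy_split", split_dataset(toy_patchset(), 0.2, rng_seed = 11))
}

# one short-trained classifier shared by the detection/counting tests
toy_classifier <- function() {
  memo_fixture("toy_classifier", {
    sp <- toy_split()
    train_classifier(sp$train, sp$test,
                     classifier_config(batch_size = 16L,
                                       total_iterations = 120L,
                                       eval_interval = 30L, rng_seed = 5))
  })
}

small_scene_params <- function(seed, ...) {
  ear_scene_params(image_size = c(576, 320),
                   kernels_per_column = c(10, 12),
                   visible_columns = c(7, 8),
                   kernel_radius = c(6, 7),
                   rng_seed = seed, ...)
}

small_scene <- function(seed = 7) {
  memo_fixture(paste0("small_scene_", seed),
               render_ear_image(small_scene_params(seed)))
}

# kernel patches with centers from a small scene, for regressor tests
scene_kernel_patches <- function() {
  memo_fixture("scene_kernel_patches", {
    patches <- c(extract_positive_patches(small_scene(7), margin = 2),
                 extract_positive_patches(small_scene(8), margin = 2))
    patch_dataset(patches, rng_seed = 7)
  })
}

blank_image <- function(value = 128L, H = 128L, W = 96L) {
  array(as.integer(value), c(H, W, 3L))
}
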