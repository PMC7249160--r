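# Patch dataset construction: the single-kernel labeling rule, center
# transforms through crops and flips, augmentation bookkeeping, splits.

test_that("well-separated kernels each yield one positive patch", {
  img <- small_scene(7)
  pos <- extract_positive_patches(img, margin = 2)
  expect_equal(length(pos), nrow(img$centers))
  expect_true(all(vapply(pos, `[[`, character(1), "label") == "kernel"))
  expect_true(all(vapply(pos, function(p) !is.null(p$center), logical(1))))
})

test_that("a crop that would capture two kernels is never a positive", {
  px <- array(100L, c(100, 100, 3))
  centers <- rbind(c(50, 50), c(52, 50))       # 2 px apart
  boxes <- cbind(centers[, 1] - 8, centers[, 2] - 8, 16, 16)
  img <- annotated_image(px, centers, boxes)
  expect_length(extract_positive_patches(img, margin = 2), 0)
})

test_that("patch centers map back to the source kernel centers exactly", {
  imgs <- list(small_scene(7), small_scene(8))
  n_checked <- 0
  for (img in imgs) {
    pos <- extract_positive_patches(img, margin = 2)
    for (p in pos) {
      s <- p$source
      back <- c(s$x + p$center[1] * s$w / 32, s$y + p$center[2] * s$h / 32)
      expect_lt(sqrt(sum((back - img$centers[s$kernel, ])^2)), 0.5)
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 150)
})

test_that("negative sampling accepts zero- and multi-center crops only", {
  # blank image: every crop qualifies and the request is met exactly
  img <- annotated_image(blank_image(), matrix(numeric(0), ncol = 2))
  neg <- extract_negative_patches(img, n = 25, rng_seed = 9)
  expect_length(neg, 25)
  expect_true(all(vapply(neg, `[[`, character(1), "label") == "non_kernel"))
  # identical seed reproduces identical crop origins
  neg2 <- extract_negative_patches(img, n = 25, rng_seed = 9)
  origins <- function(l) t(vapply(l, function(p) c(p$source$x, p$source$y),
                                  numeric(2)))
  expect_identical(origins(neg), origins(neg2))
  # on a dense scene, no accepted crop contains exactly one center
  sc <- small_scene(7)
  neg3 <- extract_negative_patches(sc, n = 60, rng_seed = 3)
  n_centers <- vapply(neg3, function(p) p$source$n_centers, numeric(1))
  expect_true(all(n_centers != 1))
  expect_true(any(n_centers >= 2))   # multi-kernel crops do occur and qualify
})

test_that("flips move pixels and centers consistently", {
  # a marker pixel at column 4, row 16 with center on that pixel's middle
  px <- array(0L, c(32, 32, 3))
  px[17, 5, ] <- 255L
  p <- patch(px, "kernel", center = c(4.5, 16.5))
  fl <- maizecount:::flip_patch(p$pixels, p$center, flip_h = TRUE,
                                flip_v = FALSE)
  expect_equal(fl$center, c(32 - 4.5, 16.5))
  expect_equal(fl$pixels[17, 28, 1], 255L)     # column 27 (0-based) lit
  expect_equal(sum(fl$pixels), sum(px))
  # vertical flip
  fv <- maizecount:::flip_patch(p$pixels, p$center, flip_h = FALSE,
                                flip_v = TRUE)
  expect_equal(fv$center, c(4.5, 32 - 16.5))
  expect_equal(fv$pixels[16, 5, 1], 255L)
})

test_that("augmentation appends round(fraction * n) copies and keeps labels", {
  ds <- toy_patchset(20, 20, seed = 3)
  out <- augment_patches(ds$patches, fraction = 0.7, rng_seed = 2)
  expect_length(out, 40 + round(0.7 * 40))
  expect_identical(out[seq_len(40)], ds$patches)   # originals retained
  labs_orig <- vapply(ds$patches, `[[`, character(1), "label")
  labs_new <- vapply(out[41:68], `[[`, character(1), "label")
  expect_true(all(labs_new %in% labs_orig))
  pos_new <- Filter(function(p) p$label == "kernel", out[41:68])
  expect_true(all(vapply(pos_new, function(p) !is.null(p$center), logical(1))))
  # fraction 0 is a no-op
  expect_identical(augment_patches(ds$patches, 0, rng_seed = 2), ds$patches)
  # deterministic under the seed
  expect_identical(augment_patches(ds$patches, 0.5, rng_seed = 4),
                   augment_patches(ds$patches, 0.5, rng_seed = 4))
})

test_that("splits partition the dataset with round-to-nearest test size", {
  ds <- toy_patchset(51, 50, seed = 5)
  sp <- split_dataset(ds, 0.2, rng_seed = 6)
  expect_equal(length(sp$test), round(0.2 * 101))
  expect_equal(length(sp$train) + length(sp$test), 101)
  # membership is disjoint and reproducible
  key <- function(p) paste(p$label, sum(as.numeric(p$pixels)))
  k_train <- vapply(sp$train$patches, key, character(1))
  k_test <- vapply(sp$test$patches, key, character(1))
  sp2 <- split_dataset(ds, 0.2, rng_seed = 6)
  expect_identical(vapply(sp2$test$patches, key, character(1)), k_test)
  expect_error(split_dataset(ds, 0), "between 0 and 1")
  expect_error(split_dataset(ds, 0.001), "empty")
})

test_that("patch objects validate their invariants", {
  expect_error(patch(array(0L, c(16, 16, 3)), "kernel"), "32 x 32 x 3")
  expect_error(patch(array(0L, c(32, 32, 3)), "non_kernel", center = c(1, 1)),
               "center")
  expect_error(patch(array(0L, c(32, 32, 3)), "kernel", center = c(33, 0)),
               "32")
})
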