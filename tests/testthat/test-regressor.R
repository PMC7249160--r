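# The center-regression CNN, the smooth-L1 loss, and the patch-to-image
# coordinate mapping.

test_that("regressor layer shapes follow the reference architecture", {
  m <- build_cnn_regressor(rng_seed = 1)
  shapes <- classifier_layer_shapes(m)
  expected <- list(c(30, 30, 32), c(28, 28, 32), c(14, 14, 32),
                   c(12, 12, 64), c(10, 10, 64), c(8, 8, 64), c(4, 4, 64),
                   c(1, 1, 100), c(1, 1, 50), c(1, 1, 10), c(1, 1, 2))
  expect_equal(lapply(shapes, as.integer), lapply(expected, as.integer))
})

test_that("smooth-L1 matches its closed form and is smooth at the knee", {
  expect_equal(smooth_l1_loss(c(0, 0), c(0, 0)), 0)
  expect_equal(smooth_l1_loss(c(0.5, 0), c(0, 0)), 0.125)
  expect_equal(smooth_l1_loss(c(2, -1), c(0, 0)), 2.0)
  # both branches give 0.5 at |d| = 1
  eps <- 1e-9
  expect_equal(smooth_l1_loss(c(1 - eps, 0), c(0, 0)), 0.5, tolerance = 1e-6)
  expect_equal(smooth_l1_loss(c(1 + eps, 0), c(0, 0)), 0.5, tolerance = 1e-6)
  # monotone non-decreasing in |d| per coordinate
  d <- seq(0, 5, by = 0.01)
  v <- vapply(d, function(x) smooth_l1_loss(c(x, 0), c(0, 0)), numeric(1))
  expect_true(all(diff(v) >= 0))
  expect_error(smooth_l1_loss(c(NA, 0), c(0, 0)), "finite")
  expect_error(smooth_l1_loss(c(Inf, 0), c(0, 0)), "finite")
})

test_that("short training reduces the loss deterministically", {
  ds <- scene_kernel_patches()
  sp <- split_dataset(ds, 0.2, rng_seed = 3)
  cfg <- regressor_config(batch_size = 24L, total_iterations = 60L,
                          eval_interval = 20L, rng_seed = 13)
  f1 <- train_regressor(sp$train, sp$test, cfg)
  h <- f1$history
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  f2 <- train_regressor(sp$train, sp$test, cfg)
  expect_identical(f1$history, f2$history)
  # predictions are clamped into the patch and deterministic
  p <- sp$test$patches[[1]]
  pr <- predict_center(f1, p)
  expect_true(all(pr$patch_xy >= 0 & pr$patch_xy < 32))
  expect_identical(predict_center(f1, p)$patch_xy, pr$patch_xy)
})

test_that("training rejects patches without centers", {
  no_center <- patch_dataset(list(
    patch(array(0L, c(32, 32, 3)), "non_kernel"),
    patch(array(0L, c(32, 32, 3)), "kernel", center = c(1, 1))))
  expect_error(train_regressor(no_center, config = regressor_config()),
               "center")
})

test_that("patch centers map into image coordinates through the window", {
  w <- list(x = 100, y = 50, width = 22, height = 32)
  expect_equal(center_to_image_coords(c(16, 16), w),
               c(x = 100 + 16 * 22 / 32, y = 66))
  expect_equal(center_to_image_coords(c(0, 0), w), c(x = 100, y = 50))
  # the map inverts the image -> patch transform to machine precision
  img_pt <- c(107.3, 61.9)
  patch_pt <- c((img_pt[1] - w$x) * 32 / w$width,
                (img_pt[2] - w$y) * 32 / w$height)
  expect_equal(unname(center_to_image_coords(patch_pt, w)), img_pt,
               tolerance = 1e-9)
  # a center_prediction comes back annotated with image coordinates
  pr <- structure(list(patch_xy = c(x = 16, y = 16), image_xy = NULL),
                  class = "center_prediction")
  out <- center_to_image_coords(pr, w)
  expect_equal(unname(out$image_xy), c(111, 66))
})
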