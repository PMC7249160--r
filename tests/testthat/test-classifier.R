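# The kernel-classification CNN, the HOG+SVM baseline, and the
# confusion-derived metrics.

test_that("classifier layer shapes follow the reference architecture", {
  m <- build_cnn_classifier(rng_seed = 1)
  shapes <- classifier_layer_shapes(m)
  expected <- list(c(30, 30, 32), c(28, 28, 32), c(14, 14, 32),
                   c(12, 12, 64), c(10, 10, 64), c(8, 8, 64), c(2, 2, 64),
                   c(1, 1, 256), c(1, 1, 128), c(1, 1, 1))
  expect_equal(lapply(shapes, as.integer), lapply(expected, as.integer))
})

test_that("training separates a color-coded toy problem perfectly", {
  sp <- toy_split()
  clf <- toy_classifier()
  h <- clf$history
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  te <- maizecount:::patches_to_matrix(sp$test)
  pred <- predict_confidence(clf, sp$test)
  m <- classification_metrics(te$y, pred >= 0.5)
  expect_equal(m$accuracy, 1.0)
  expect_equal(m$f_score, 1.0)
})

test_that("confidences are probabilities and batching matches per-patch calls", {
  clf <- toy_classifier()
  sp <- toy_split()
  ps <- sp$test$patches[1:8]
  batched <- predict_confidence(clf, ps)
  expect_true(all(batched >= 0 & batched <= 1))
  single <- vapply(ps, function(p) predict_confidence(clf, p), numeric(1))
  expect_equal(batched, single, tolerance = 1e-5)
  # inference is deterministic: the same patch scores identically
  expect_identical(predict_confidence(clf, ps[[1]]),
                   predict_confidence(clf, ps[[1]]))
})

test_that("inference-mode batch-norm folding is algebraically exact", {
  clf <- toy_classifier()
  X <- maizecount:::patches_to_matrix(toy_split()$test$patches[1:6])$X
  unfolded <- maizecount:::cnn_forward(clf$net, X, training = FALSE)$out
  folded <- maizecount:::cnn_predict(clf$net, X)
  expect_equal(folded, unfolded, tolerance = 1e-12)
})

test_that("seeded training reproduces the loss history bit for bit", {
  ds <- toy_patchset(24, 24, seed = 8)
  cfg <- classifier_config(batch_size = 8L, total_iterations = 40L,
                           eval_interval = 10L, rng_seed = 21)
  f1 <- train_classifier(ds, config = cfg)
  f2 <- train_classifier(ds, config = cfg)
  expect_identical(f1$history, f2$history)
})

test_that("training demands both classes and predicting demands training", {
  only_pos <- patch_dataset(Filter(function(p) p$label == "kernel",
                                   toy_patchset(10, 10)$patches))
  expect_error(train_classifier(only_pos), "both")
  expect_error(hog_svm_classifier(only_pos), "both")
  expect_error(predict_confidence(build_cnn_classifier(), blank_image(0, 32, 32)),
               "untrained")
  clf <- toy_classifier()
  expect_error(predict_confidence(clf, array(0L, c(16, 16, 3))), "32 x 32 x 3")
})

test_that("HOG descriptor has the stated geometry and zero response to flats", {
  # ((32/4 - 2) + 1)^2 blocks x 2x2 cells x 9 bins
  d <- hog_descriptor(matrix(0.5, 32, 32))
  expect_length(d, 1764)
  expect_true(all(abs(d) < 1e-6))
  # gradients produce a nonzero, L2-block-normalised descriptor
  g <- hog_descriptor(matrix(rep(seq(0, 1, length.out = 32), each = 32), 32))
  expect_gt(sum(g), 0)
  expect_true(all(is.finite(g)))
})

test_that("HOG+SVM baseline solves the toy problem through the same interface", {
  sp <- toy_split()
  base <- hog_svm_classifier(sp$train)
  expect_equal(base$descriptor_length, 1764L)
  te <- maizecount:::patches_to_matrix(sp$test)
  pred <- predict_confidence(base, sp$test$patches)
  expect_true(all(pred >= 0 & pred <= 1))
  m <- classification_metrics(te$y, pred >= 0.5)
  expect_equal(m$accuracy, 1.0)
})

test_that("metric arithmetic satisfies accuracy = 1 - (fp + fn)/n", {
  for (s in 1:20) {
    maizecount:::with_seed(s, {
      n <- sample(10:200, 1)
      y <- sample(0:1, n, replace = TRUE)
      p <- sample(0:1, n, replace = TRUE)
      if (sum(y) == 0 || sum(p) == 0) p[1] <- y[1] <- 1
      m <- classification_metrics(y, p)
      expect_equal(m$accuracy, 1 - (m$fp + m$fn) / m$n)
      tp <- sum(y == 1 & p == 1)
      expect_equal(m$f_score, 2 * tp / (2 * tp + m$fp + m$fn))
    })
  }
  expect_error(classification_metrics(c(1, 0), c(1)), "equal length")
  expect_warning(m0 <- classification_metrics(c(0, 0), c(0, 0)), "F-score")
  expect_equal(m0$f_score, 0)
})
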