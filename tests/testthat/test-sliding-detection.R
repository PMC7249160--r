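# Window enumeration, IOU, greedy NMS (against a brute-force oracle), and
# window scoring.

test_that("window enumeration counts and orders origins as a raster scan", {
  w <- enumerate_windows(c(64, 44), c(32, 22), c(4, 4))
  expect_equal(nrow(w), 6 * 9)
  # row-major: x varies fastest
  expect_equal(w[1:3, "x"], c(0, 4, 8))
  expect_equal(w[1:3, "y"], c(0, 0, 0))
  expect_equal(nrow(enumerate_windows(c(32, 22), c(32, 22), c(4, 4))), 1)
  expect_equal(unname(enumerate_windows(c(32, 22), c(32, 22), c(4, 4))[1, ]),
               c(0, 0))
  expect_equal(nrow(enumerate_windows(c(31, 44), c(32, 22), c(4, 4))), 0)
})

test_that("IOU matches area arithmetic on half-open boxes", {
  expect_equal(iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1.0)
  expect_equal(iou(c(0, 0, 2, 2), c(5, 5, 2, 2)), 0.0)
  expect_equal(iou(c(0, 0, 2, 2), c(1, 1, 2, 2)), 1 / 7)
  expect_error(iou(c(0, 0, 0, 2), c(0, 0, 2, 2)), "positive area")
})

test_that("IOU is symmetric and bounded on random box pairs", {
  maizecount:::with_seed(99, {
    for (i in 1:100) {
      a <- c(runif(2, 0, 50), runif(2, 0.5, 20))
      b <- c(runif(2, 0, 50), runif(2, 0.5, 20))
      v <- iou(a, b)
      expect_equal(v, iou(b, a))
      expect_gte(v, 0); expect_lte(v, 1)
    }
  })
  # vectorised helper agrees with the scalar definition in bulk
  boxes <- random_scored_boxes(100, seed = 5)
  m <- cbind(boxes$x, boxes$y, boxes$width, boxes$height)
  bulk <- maizecount:::iou_one_vs_many(m[1, ], m)
  ref <- vapply(seq_len(100), function(i) iou(m[1, ], m[i, ]), numeric(1))
  expect_equal(bulk, ref)
  expect_equal(sum(abs(bulk - ref) > 0), 0)
})

test_that("greedy NMS keeps the right boxes in the right order", {
  one <- data.frame(x = 1, y = 2, width = 5, height = 5, confidence = 0.7)
  expect_equal(nms(one, 0.5), one)
  dup <- rbind(one, transform(one, confidence = 0.9))
  kept <- nms(dup, 0.5)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$confidence, 0.9)
  # empty input passes through
  expect_equal(nrow(nms(one[0, ], 0.5)), 0)
})

test_that("NMS equals the brute-force transcription on random boxes", {
  for (s in 1:10) {
    boxes <- random_scored_boxes(200, seed = 100 + s)
    for (lambda in c(0.2, 0.5)) {
      got <- nms(boxes, lambda)
      want <- brute_force_nms(boxes, lambda)
      rownames(want) <- NULL
      expect_equal(got, want)
    }
  }
})

test_that("NMS output is order-invariant, idempotent, and mutually below lambda", {
  boxes <- random_scored_boxes(150, seed = 77)
  lambda <- 0.3
  kept <- nms(boxes, lambda)
  # kept set is mutually non-overlapping beyond lambda
  m <- cbind(kept$x, kept$y, kept$width, kept$height)
  for (i in seq_len(nrow(kept))) {
    for (j in seq_len(i - 1L)) {
      expect_lte(iou(m[i, ], m[j, ]), lambda)
    }
  }
  expect_true(all(diff(kept$confidence) <= 0))
  expect_equal(nms(kept, lambda), kept)
  shuffled <- maizecount:::with_seed(1, boxes[sample.int(nrow(boxes)), ])
  expect_equal(nms(shuffled, lambda), kept)
})

test_that("scoring windows respects thresholds and rejects untrained models", {
  clf <- toy_classifier()
  img <- blank_image(100, 96, 96)   # gray: far from the kernel color
  cfg <- nms_config(stride = c(8, 8))
  scored <- score_windows(clf, img, cfg)
  expect_equal(nrow(scored), 0)
  # with threshold 0 every enumerated window comes back
  cfg0 <- nms_config(confidence_threshold = 0, stride = c(8, 8))
  all_w <- score_windows(clf, img, cfg0)
  expect_equal(nrow(all_w), nrow(enumerate_windows(c(96, 96), c(32, 22), c(8, 8))))
  expect_true(all(all_w$confidence >= 0 & all_w$confidence <= 1))
  # a kernel-like yellow blob on a dark backdrop draws high-confidence windows
  blob <- blank_image(60L, 64, 64)
  yy <- rep(1:64, 64); xx <- rep(1:64, each = 64)
  inside <- ((xx - 32) / 10)^2 + ((yy - 32) / 13)^2 <= 1
  for (c in 1:3) {
    ch <- blob[, , c]
    ch[inside] <- c(230L, 190L, 60L)[c]
    blob[, , c] <- ch
  }
  hot <- score_windows(clf, blob, cfg)
  expect_gt(nrow(hot), 0)
  expect_error(score_windows(build_cnn_classifier(), img, cfg), "untrained")
})
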