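# Count extrapolation, counting metrics, center matching, and the pipeline
# composition on degenerate inputs.

test_that("extrapolation rounds half away from zero and stays monotone", {
  expect_equal(extrapolate_total(0, 2.5), 0L)
  expect_equal(extrapolate_total(100, 2.5), 250L)
  expect_equal(extrapolate_total(101, 2.5), 253L)   # 252.5 rounds up
  expect_equal(extrapolate_total(10, 1.0), 10L)
  n <- 0:200
  tot <- vapply(n, extrapolate_total, integer(1), factor = 2.5)
  expect_true(all(diff(tot) >= 0))
  expect_true(all(abs(tot - 2.5 * n) <= 0.5))       # linear before rounding
  expect_error(extrapolate_total(-1, 2.5), "n_detected")
  expect_error(extrapolate_total(5, 0), "factor")
})

test_that("counting metrics reproduce direct formula evaluation", {
  m <- count_metrics(c(1012, 312, 550, 342, 390), c(1046, 323, 585, 296, 394))
  expect_equal(m$mae, (34 + 11 + 35 + 46 + 4) / 5)
  expect_equal(m$rmse, sqrt((34^2 + 11^2 + 35^2 + 46^2 + 4^2) / 5))
  expect_equal(m$rmse, sqrt(4634 / 5), tolerance = 1e-12)
  expect_gte(m$correlation, -1); expect_lte(m$correlation, 1)
  p <- c(100, 200, 300)
  mm <- count_metrics(p, p)
  expect_equal(mm$rmse, 0); expect_equal(mm$mae, 0)
  expect_equal(mm$correlation, 1)
  expect_error(count_metrics(1:3, 1:2), "equal length")
  expect_error(count_metrics(c(1), c(1)), "two pairs")
  expect_error(count_metrics(c(5, 5), c(1, 2)), "zero variance")
})

test_that("rmse is never below mae", {
  for (s in 1:1000) {
    maizecount:::with_seed(s, {
      n <- sample(2:20, 1)
      p <- runif(n, 0, 1000); a <- runif(n, 0, 1000)
      err <- p - a
      expect_gte(sqrt(mean(err^2)), mean(abs(err)))
    })
  }
})

test_that("center matching is one-to-one within tolerance", {
  truth <- rbind(c(10, 10), c(30, 10), c(50, 10))
  pred <- rbind(c(11, 10), c(29, 11), c(80, 80))
  mm <- match_centers(pred, truth, tolerance = 3)
  expect_equal(mm$n_matched, 2)
  expect_equal(mm$recall, 2 / 3)
  expect_equal(mm$fp_rate, 1 / 3)
  # two predictions cannot claim the same truth center
  pred2 <- rbind(c(10, 10), c(10.5, 10))
  mm2 <- match_centers(pred2, truth, tolerance = 3)
  expect_equal(mm2$n_matched, 1)
  expect_equal(mm2$fp_rate, 1 / 2)
  tr <- as.vector(mm2$matches[, "truth"])
  expect_equal(tr, unique(tr))
})

test_that("the pipeline returns an empty, consistent estimate on a blank image", {
  clf <- toy_classifier()
  est <- count_kernels(blank_image(100, 96, 96), clf,
                       config = nms_config(stride = c(8, 8)))
  expect_s3_class(est, "count_estimate")
  expect_equal(est$n_detected, 0)
  expect_equal(est$total, 0L)
  expect_equal(nrow(est$centers), 0)
  expect_equal(nrow(est$boxes), est$n_detected)
  expect_error(count_kernels(blank_image(), build_cnn_classifier()),
               "untrained")
})

test_that("every kept window yields exactly one center inside it", {
  clf <- toy_classifier()
  # kernel-colored disc on gray: windows over the disc score high
  img <- blank_image(100, 96, 96)
  yy <- rep(1:96, 96); xx <- rep(1:96, each = 96)
  disc <- (yy - 48)^2 + (xx - 48)^2 <= 14^2
  for (c in 1:3) {
    ch <- img[, , c]
    ch[disc] <- c(230, 190, 60)[c]
    img[, , c] <- ch
  }
  est <- count_kernels(img, clf, config = nms_config(stride = c(4, 4)))
  expect_equal(nrow(est$centers), est$n_detected)
  if (est$n_detected > 0) {
    inside <- est$centers[, "x"] >= est$boxes$x &
      est$centers[, "x"] < est$boxes$x + est$boxes$width &
      est$centers[, "y"] >= est$boxes$y &
      est$centers[, "y"] < est$boxes$y + est$boxes$height
    expect_true(all(inside))
    expect_equal(est$total, extrapolate_total(est$n_detected, 2.5))
  }
})
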