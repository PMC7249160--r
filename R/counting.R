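# End-to-end composition: scan -> threshold -> NMS -> center regression ->
# count, the symmetric-ear extrapolation of the visible-side count, and the
# counting accuracy metrics (RMSE / MAE / Pearson correlation).

#' Detect and count kernels in an ear image
#'
#' Runs the full pipeline: score all sliding windows with the classifier,
#' apply greedy NMS, regress the kernel center inside each kept window, and
#' extrapolate the visible-side detection count to a whole-ear estimate with
#' the symmetric-ear factor.
#'
#' @param image An [annotated_image()] or `H x W x 3` array.
#' @param classifier A trained `kernel_classifier`.
#' @param regressor A trained `center_regressor` (optional; without it the
#'   window midpoints are reported as centers).
#' @param config An [nms_config()].
#' @param factor Extrapolation factor from visible-side count to whole-ear
#'   count; the default 2.5 encodes the assumption that the camera-facing
#'   side shows 40% of the ear's kernel columns (about two columns on each
#'   edge are hidden).
#'
#' @return Object of class `count_estimate`: `n_detected` (post-NMS kernel
#'   windows), `factor`, `total` (= `round(factor * n_detected)`, half away
#'   from zero), `centers` (one (x, y) per detection) and the kept `boxes`.
#' @export
count_kernels <- function(image, classifier, regressor = NULL,
                          config = nms_config(), factor = 2.5) {
  stopifnot(inherits(classifier, "kernel_classifier"))
  if (!classifier$trained) stop("classifier is untrained", call. = FALSE)
  if (!is.null(regressor)) {
    stopifnot(inherits(regressor, "center_regressor"))
    if (!regressor$trained) stop("regressor is untrained", call. = FALSE)
  }
  scored <- score_windows(classifier, image, config)
  kept <- nms(scored, config$overlap_threshold)
  n_det <- nrow(kept)
  centers <- matrix(numeric(0), ncol = 2L,
                    dimnames = list(NULL, c("x", "y")))
  if (n_det > 0) {
    pixels <- if (inherits(image, "annotated_image")) image$pixels else image
    X <- windows_to_matrix(pixels, cbind(x = kept$x, y = kept$y),
                           config$window[1], config$window[2])
    patch_xy <- if (is.null(regressor)) {
      matrix(PATCH_SIZE / 2, 2L, n_det)
    } else {
      out <- cnn_predict(regressor$net, X) * PATCH_SIZE
      pmin(pmax(out, 0), PATCH_SIZE - 1e-9)
    }
    centers <- cbind(x = kept$x + patch_xy[1, ] * kept$width / PATCH_SIZE,
                     y = kept$y + patch_xy[2, ] * kept$height / PATCH_SIZE)
  }
  structure(list(n_detected = n_det, factor = factor,
                 total = extrapolate_total(n_det, factor),
                 centers = centers, boxes = kept),
            class = "count_estimate")
}

#' @export
print.count_estimate <- function(x, ...) {
  cat(sprintf("Kernel count: %d detected on the visible side x %.2f -> %d total\n",
              x$n_detected, x$factor, x$total))
  invisible(x)
}

#' Extrapolate a visible-side kernel count to a whole-ear estimate
#'
#' Multiplies the detected one-side count by the symmetric-ear factor and
#' rounds half away from zero (so 101 detections at factor 2.5 give 253).
#'
#' @param n_detected Non-negative detection count.
#' @param factor Positive extrapolation factor (2.5 by default).
#'
#' @return Integer whole-ear estimate.
#' @export
#' @examples
#' extrapolate_total(100, 2.5)  # 250
#' extrapolate_total(101, 2.5)  # 253
extrapolate_total <- function(n_detected, factor = 2.5) {
  stopifnot_scalar(n_detected, "n_detected", lower = 0)
  stopifnot_scalar(factor, "factor", lower = 1e-12)
  as.integer(round_half_away(factor * n_detected))
}

#' Counting accuracy metrics
#'
#' Root-mean-squared error, mean absolute error (both in kernels) and the
#' Pearson product-moment correlation between predicted and actual counts.
#' The correlation is conventionally displayed multiplied by 100.
#'
#' @param predicted,actual Equal-length numeric vectors of counts (length >=
#'   2 so the correlation is defined).
#'
#' @return Object of class `count_metrics` with `rmse`, `mae`, `correlation`.
#' @export
#' @examples
#' count_metrics(c(1012, 312, 550, 342, 390), c(1046, 323, 585, 296, 394))
count_metrics <- function(predicted, actual) {
  predicted <- as.numeric(predicted); actual <- as.numeric(actual)
  if (length(predicted) != length(actual)) {
    stop("`predicted` and `actual` must have equal length", call. = FALSE)
  }
  if (length(predicted) < 2L) {
    stop("need at least two pairs of counts", call. = FALSE)
  }
  if (stats::sd(predicted) == 0 || stats::sd(actual) == 0) {
    stop("correlation undefined: zero variance in the counts", call. = FALSE)
  }
  err <- predicted - actual
  structure(list(rmse = sqrt(mean(err^2)), mae = mean(abs(err)),
                 correlation = cor(predicted, actual),
                 n = length(predicted)),
            class = "count_metrics")
}

#' @export
print.count_metrics <- function(x, ...) {
  cat(sprintf("Counting over %d ears: RMSE %.2f, MAE %.2f, correlation %.2f (x100)\n",
              x$n, x$rmse, x$mae, 100 * x$correlation))
  invisible(x)
}

#' Greedily match predicted centers to ground-truth centers
#'
#' One-to-one matching: predictions (in the given order, normally by
#' decreasing confidence) claim the nearest unclaimed ground-truth center
#' within `tolerance` pixels. Used to score detection recall and the false
#' positive rate against the generator's annotations.
#'
#' @param predicted `n x 2` matrix of predicted (x, y) centers.
#' @param truth `m x 2` matrix of ground-truth centers.
#' @param tolerance Maximum Euclidean match distance in pixels.
#'
#' @return List: `recall` (matched / m), `fp_rate` (unmatched predictions /
#'   n), `n_matched`, and the `matches` index matrix (prediction row,
#'   truth row).
#' @export
match_centers <- function(predicted, truth, tolerance) {
  predicted <- matrix(as.numeric(predicted), ncol = 2L)
  truth <- matrix(as.numeric(truth), ncol = 2L)
  n <- nrow(predicted); m <- nrow(truth)
  taken <- rep(FALSE, m)
  matches <- matrix(integer(0), ncol = 2L,
                    dimnames = list(NULL, c("pred", "truth")))
  for (i in seq_len(n)) {
    if (m == 0L) break
    d2 <- (truth[, 1] - predicted[i, 1])^2 + (truth[, 2] - predicted[i, 2])^2
    d2[taken] <- Inf
    j <- which.min(d2)
    if (d2[j] <= tolerance^2) {
      taken[j] <- TRUE
      matches <- rbind(matches, c(i, j))
    }
  }
  k <- nrow(matches)
  list(recall = if (m > 0) k / m else NA_real_,
       fp_rate = if (n > 0) (n - k) / n else 0,
       n_matched = k, matches = matches)
}

#' Seeded end-to-end recovery study on synthetic scenes
#'
#' Reproduces the full pipeline at desk scale on data from the synthetic
#' generator: trains the classifier and regressor on patches cut from
#' training scenes, then detects and counts kernels on held-out evaluation
#' scenes, scoring detection recall, the false-positive rate, the
#' whole-ear count error against the generator's ground truth, and the
#' held-out center-regression error.
#'
#' Problem sizes (the package's desk-scale defaults): 6 training scenes and
#' `n_scenes = 10` evaluation scenes of a single ear with 11-13 visible
#' kernel columns of 18-24 kernels (roughly 200-310 visible kernels);
#' about 4,000 training patches after 70% flip/color augmentation; 400
#' classifier iterations at batch 48 and 450 regressor iterations at batch
#' 45 (both converge well before that on this separable synthetic data);
#' detection stride 8 px.
#'
#' @param seed Master seed; every random stage derives its seed from it.
#' @param n_scenes Number of evaluation scenes.
#' @param n_train_scenes Number of training scenes.
#' @param classifier_iterations,regressor_iterations Training lengths.
#' @param stride Detection stride in pixels.
#' @param factor Extrapolation factor.
#' @param verbose Log progress.
#'
#' @return List with overall metrics (`recall`, `fp_rate`,
#'   `center_error_px`, `count_metrics`, `scenes_within_15pct`, the
#'   classifier's held-out `classifier_metrics`), a per-scene data frame
#'   (`scenes`), and the trained models.
#' @export
kernel_recovery_study <- function(seed = 1L, n_scenes = 10L,
                                  n_train_scenes = 6L,
                                  classifier_iterations = 400L,
                                  regressor_iterations = 450L,
                                  stride = 8L, factor = 2.5,
                                  verbose = FALSE) {
  say <- function(...) if (verbose) log_msg(...)
  seeds <- derive_seeds(seed, 6L + n_train_scenes + n_scenes)
  scene_params <- function(s) {
    ear_scene_params(image_size = c(1024, 544),
                     kernels_per_column = c(18, 24),
                     visible_columns = c(11, 13),
                     kernel_radius = c(10, 12),
                     ear_tilt = c(-10, 10),
                     background_class = "random",
                     rng_seed = s)
  }
  # --- training patches
  say("generating %d training scenes", n_train_scenes)
  pos <- list(); neg <- list()
  for (i in seq_len(n_train_scenes)) {
    img <- render_ear_image(scene_params(seeds[6L + i]))
    pos <- c(pos, extract_positive_patches(img, margin = 2))
    neg <- c(neg, extract_negative_patches(img, n = 180L,
                                           rng_seed = seeds[6L + i]))
  }
  say("extracted %d positive and %d negative patches", length(pos), length(neg))
  patches <- augment_patches(c(pos, neg), fraction = 0.7, rng_seed = seeds[1])
  ds <- patch_dataset(patches, rng_seed = seeds[1])
  split <- split_dataset(ds, test_fraction = 0.2, rng_seed = seeds[2])
  say("training classifier on %d patches (%d held out)",
      length(split$train), length(split$test))
  clf <- train_classifier(split$train, split$test,
                          classifier_config(batch_size = 48L,
                                            total_iterations = classifier_iterations,
                                            rng_seed = seeds[3]))
  clf_te <- patches_to_matrix(split$test)
  clf_metrics <- classification_metrics(clf_te$y,
                                        predict_confidence(clf, split$test) >= 0.5)
  # --- regressor on positive patches only
  pos_ds <- patch_dataset(pos, rng_seed = seeds[4])
  pos_split <- split_dataset(pos_ds, test_fraction = 0.2, rng_seed = seeds[4])
  say("training regressor on %d kernel patches", length(pos_split$train))
  reg <- train_regressor(pos_split$train, pos_split$test,
                         regressor_config(batch_size = 45L,
                                          total_iterations = regressor_iterations,
                                          rng_seed = seeds[5]))
  te <- patches_to_matrix(pos_split$test)
  pred_xy <- pmin(pmax(cnn_predict(reg$net, te$X) * PATCH_SIZE, 0),
                  PATCH_SIZE - 1e-9)
  center_err <- mean(sqrt(colSums((pred_xy - te$centers)^2)))
  say("held-out center error %.2f px", center_err)
  # --- evaluation scenes
  cfg <- nms_config(stride = c(stride, stride))
  res <- data.frame(scene = integer(0), visible = integer(0),
                    truth_total = integer(0), n_detected = integer(0),
                    est_total = integer(0), recall = numeric(0),
                    fp_rate = numeric(0))
  for (i in seq_len(n_scenes)) {
    sp <- scene_params(seeds[6L + n_train_scenes + i])
    img <- render_ear_image(sp)
    est <- count_kernels(img, clf, reg, cfg, factor = factor)
    tol <- 0.5 * 2.2 * mean(sp$kernel_radius)   # half the column spacing
    mm <- match_centers(est$centers, img$centers, tolerance = tol)
    res <- rbind(res, data.frame(scene = i, visible = nrow(img$centers),
                                 truth_total = img$total_kernels,
                                 n_detected = est$n_detected,
                                 est_total = est$total,
                                 recall = mm$recall, fp_rate = mm$fp_rate))
    say("scene %d: %d/%d detected (recall %.3f, fp %.3f), count %d vs %d",
        i, est$n_detected, nrow(img$centers), mm$recall, mm$fp_rate,
        est$total, img$total_kernels)
  }
  cm <- count_metrics(res$est_total, res$truth_total)
  within15 <- sum(abs(res$est_total - res$truth_total) <=
                    0.15 * res$truth_total)
  list(recall = mean(res$recall), fp_rate = mean(res$fp_rate),
       center_error_px = center_err, count_metrics = cm,
       scenes_within_15pct = within15, scenes = res,
       classifier_metrics = clf_metrics,
       classifier = clf, regressor = reg)
}
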