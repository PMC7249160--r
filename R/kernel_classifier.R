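# The kernel/non-kernel patch classifier: a 10-layer CNN on 32x32 RGB
# patches with batch normalization and ReLU after every layer and a sigmoid
# confidence head, trained with Adam on the log loss; plus a HOG+SVM baseline
# and the confusion-derived classification metrics.

#' Training configuration for the kernel classifier
#'
#' Defaults reproduce the reference training protocol: mini-batch 128, 25,000
#' iterations, learning rate 3e-4 (0.03%) reduced to 1e-4 (0.01%) when the
#' test loss plateaus, Adam on the log loss, Xavier initialization. Desk-scale
#' experiments pass smaller `total_iterations`/`batch_size`.
#'
#' @param batch_size Mini-batch size (>= 1).
#' @param total_iterations Number of mini-batch updates.
#' @param lr_initial,lr_reduced Initial and post-plateau Adam learning rates
#'   (`0 < lr_reduced <= lr_initial`).
#' @param plateau_patience Number of consecutive test-loss evaluations without
#'   improvement (> `plateau_tol`) that triggers the one-time rate drop.
#' @param eval_interval Iterations between test-loss evaluations.
#' @param plateau_tol Minimal decrease of the test loss that counts as an
#'   improvement.
#' @param rng_seed Seed covering initialization and batch sampling.
#'
#' @return Object of class `classifier_config`.
#' @export
classifier_config <- function(batch_size = 128L, total_iterations = 25000L,
                              lr_initial = 3e-4, lr_reduced = 1e-4,
                              plateau_patience = 5L, eval_interval = 100L,
                              plateau_tol = 1e-4, rng_seed = 1L) {
  stopifnot_scalar(batch_size, "batch_size", lower = 1)
  stopifnot_scalar(total_iterations, "total_iterations", lower = 1)
  stopifnot_scalar(lr_initial, "lr_initial", lower = 1e-12)
  stopifnot_scalar(lr_reduced, "lr_reduced", lower = 1e-12, upper = lr_initial)
  stopifnot_scalar(plateau_patience, "plateau_patience", lower = 1)
  stopifnot_scalar(eval_interval, "eval_interval", lower = 1)
  stopifnot_scalar(rng_seed, "rng_seed")
  structure(list(batch_size = as.integer(batch_size),
                 total_iterations = as.integer(total_iterations),
                 lr_initial = lr_initial, lr_reduced = lr_reduced,
                 plateau_patience = as.integer(plateau_patience),
                 eval_interval = as.integer(eval_interval),
                 plateau_tol = plateau_tol,
                 rng_seed = as.integer(rng_seed)),
            class = "classifier_config")
}

classifier_specs <- function() {
  list(conv_spec(32), bn_spec(), relu_spec(),
       conv_spec(32), bn_spec(), relu_spec(),
       avgpool_spec(2L, 2L), bn_spec(), relu_spec(),
       conv_spec(64), bn_spec(), relu_spec(),
       conv_spec(64), bn_spec(), relu_spec(),
       conv_spec(64), bn_spec(), relu_spec(),
       avgpool_spec(7L, 1L), bn_spec(), relu_spec(),
       fc_spec(256L), bn_spec(), relu_spec(),
       fc_spec(128L), bn_spec(), relu_spec(),
       fc_spec(1L))
}

#' Build the (untrained) kernel-classification CNN
#'
#' The architecture on a 32x32x3 input: two 3x3/32 convolutions (30x30x32,
#' 28x28x32), 2x2 average pool stride 2 (14x14x32), three 3x3/64 convolutions
#' (12x12x64, 10x10x64, 8x8x64), 7x7 average pool stride 1 (2x2x64), then
#' fully connected layers of 256, 128 and 1 unit with a sigmoid confidence
#' output. Every layer except the sigmoid head is followed by batch
#' normalization and ReLU; convolutions are unpadded, stride 1. Weights are
#' Xavier-initialized under `rng_seed`.
#'
#' @param rng_seed Seed for the weight initialization.
#' @return Object of class `kernel_classifier` (untrained).
#' @export
#' @examples
#' m <- build_cnn_classifier(rng_seed = 7)
#' classifier_layer_shapes(m)[1:3]
build_cnn_classifier <- function(rng_seed = 1L) {
  net <- with_seed(rng_seed, new_cnn(classifier_specs(), c(32L, 32L, 3L),
                                     out_activation = "sigmoid"))
  structure(list(net = net, trained = FALSE, history = NULL, config = NULL,
                 rng_seed = as.integer(rng_seed)),
            class = "kernel_classifier")
}

#' Per-layer output shapes of a classifier or regressor
#'
#' @param model A `kernel_classifier` or `center_regressor`.
#' @return List of `(H, W, C)` integer vectors, one per parameterized or
#'   pooling layer (batch norm and ReLU preserve shape and are omitted).
#' @export
classifier_layer_shapes <- function(model) {
  net <- model$net
  keep <- vapply(net$layers, function(l) {
    l$type %in% c("conv", "avgpool", "maxpool", "fc")
  }, logical(1))
  lapply(net$layers[keep], `[[`, "out_shape")
}

# shared mini-batch trainer for both CNNs; `head` computes (loss, dZ) at the
# final layer's pre-activation output.
run_training <- function(net, Xtr, T_tr, Xte, T_te, iterations, batch_size,
                         lr_schedule, eval_interval, head) {
  n <- ncol(Xtr)
  batch_size <- min(batch_size, n)
  perm <- sample.int(n)
  pos <- 1L
  hist_iter <- integer(0); hist_train <- numeric(0); hist_test <- numeric(0)
  hist_lr <- numeric(0)
  run_loss <- 0; run_n <- 0L
  best_test <- Inf; stall <- 0L; reduced <- FALSE
  lr <- lr_schedule$initial
  for (it in seq_len(iterations)) {
    if (pos + batch_size - 1L > n) { perm <- sample.int(n); pos <- 1L }
    idx <- perm[pos:(pos + batch_size - 1L)]
    pos <- pos + batch_size
    fw <- cnn_forward_train(net, Xtr[, idx, drop = FALSE])
    net <- fw$net
    hd <- head(fw$out, T_tr[, idx, drop = FALSE])
    grads <- cnn_backward(net, fw$caches, hd$dZ, fw$acts)
    net <- adam_step(net, grads, lr)
    run_loss <- run_loss + hd$loss; run_n <- run_n + 1L
    if (it %% eval_interval == 0L || it == iterations) {
      test_loss <- if (!is.null(Xte) && ncol(Xte) > 0) {
        zo <- cnn_predict(net, Xte)
        head(zo, T_te)$loss
      } else NA_real_
      hist_iter <- c(hist_iter, it)
      hist_train <- c(hist_train, run_loss / max(run_n, 1L))
      hist_test <- c(hist_test, test_loss)
      hist_lr <- c(hist_lr, lr)
      run_loss <- 0; run_n <- 0L
      if (!reduced && !is.na(test_loss) && !is.null(lr_schedule$reduced)) {
        if (test_loss < best_test - lr_schedule$tol) {
          best_test <- test_loss; stall <- 0L
        } else {
          stall <- stall + 1L
          if (stall >= lr_schedule$patience) {
            lr <- lr_schedule$reduced; reduced <- TRUE
          }
        }
        if (test_loss < best_test) best_test <- test_loss
      }
    }
  }
  list(net = net,
       history = data.frame(iteration = hist_iter, train_loss = hist_train,
                            test_loss = hist_test, lr = hist_lr))
}

#' Train the kernel-classification CNN
#'
#' Minimizes the binary cross-entropy with Adam over mini-batches sampled
#' without replacement within each epoch; the learning rate drops from
#' `lr_initial` to `lr_reduced` when the test loss stops improving for
#' `plateau_patience` consecutive evaluations. Training is deterministic for
#' a fixed config seed.
#'
#' @param train,test [patch_dataset()]s; `train` must contain both classes.
#' @param config A [classifier_config()].
#'
#' @return A trained `kernel_classifier` carrying the loss history
#'   (`$history`: iteration, train/test log loss, learning rate).
#' @export
train_classifier <- function(train, test = NULL, config = classifier_config()) {
  stopifnot(inherits(train, "patch_dataset"), inherits(config, "classifier_config"))
  counts <- patch_label_counts(train)
  if (any(counts == 0L)) {
    stop("training set must contain both kernel and non_kernel patches",
         call. = FALSE)
  }
  tr <- patches_to_matrix(train)
  te <- if (!is.null(test)) patches_to_matrix(test)
  head_bce <- function(z, y) {
    p <- sigmoid(z)
    list(loss = bce_loss(as.numeric(p), as.numeric(y)),
         dZ = (p - y) / ncol(z))
  }
  with_seed(config$rng_seed, {
    net <- new_cnn(classifier_specs(), c(32L, 32L, 3L), "sigmoid")
    fit <- run_training(net, tr$X, matrix(tr$y, 1L), te$X,
                        if (!is.null(te)) matrix(te$y, 1L),
                        config$total_iterations, config$batch_size,
                        list(initial = config$lr_initial,
                             reduced = config$lr_reduced,
                             patience = config$plateau_patience,
                             tol = config$plateau_tol),
                        config$eval_interval, head_bce)
    structure(list(net = fit$net, trained = TRUE, history = fit$history,
                   config = config, rng_seed = config$rng_seed),
              class = "kernel_classifier")
  })
}

#' @export
print.kernel_classifier <- function(x, ...) {
  cat("Kernel-classification CNN (32x32x3 -> sigmoid confidence)\n")
  if (x$trained) {
    h <- x$history
    cat(sprintf("  trained %d iterations; final train loss %.4f, test loss %s\n",
                max(h$iteration), h$train_loss[nrow(h)],
                ifelse(is.na(h$test_loss[nrow(h)]), "-",
                       sprintf("%.4f", h$test_loss[nrow(h)]))))
  } else {
    cat("  untrained\n")
  }
  invisible(x)
}

#' @export
plot.kernel_classifier <- function(x, ...) {
  h <- x$history
  if (is.null(h)) stop("no training history to plot", call. = FALSE)
  graphics::matplot(h$iteration, cbind(h$train_loss, h$test_loss), type = "l",
                    lty = 1, col = c("black", "red"), xlab = "iteration",
                    ylab = "log loss", ...)
  graphics::legend("topright", c("train", "test"), lty = 1,
                   col = c("black", "red"), bty = "n")
  invisible(x)
}

# patches -> 3072 x N matrix in [0, 1]; accepts a single patch, an array, a
# list of patches, or a patch_dataset.
as_patch_matrix <- function(x) {
  if (inherits(x, "kernel_patch")) x <- list(x)
  if (inherits(x, "patch_dataset") || (is.list(x) && !is.array(x))) {
    return(patches_to_matrix(x)$X)
  }
  d <- dim(x)
  if (is.null(d) && length(x) == PATCH_SIZE^2 * 3L) {
    return(matrix(as.numeric(x), ncol = 1L))
  }
  if (length(d) == 3L && all(d == c(PATCH_SIZE, PATCH_SIZE, 3L))) {
    v <- as.numeric(x)
    if (max(v) > 1) v <- v / 255
    return(matrix(v, ncol = 1L))
  }
  if (length(d) == 2L && d[1] == PATCH_SIZE^2 * 3L) return(x)
  stop("patch input must be 32 x 32 x 3 (or a list/dataset of such patches)",
       call. = FALSE)
}

#' Kernel confidence of patches
#'
#' Runs the trained classifier in inference mode (batch normalization uses
#' its accumulated running statistics), returning one confidence in `[0, 1]`
#' per patch. Batched evaluation equals per-patch evaluation.
#'
#' @param model A trained `kernel_classifier` (or `hog_svm` baseline; both
#'   models expose this same interface).
#' @param patches A [patch()], a 32x32x3 array, a list of patches, or a
#'   [patch_dataset()].
#'
#' @return Numeric vector of confidences.
#' @export
predict_confidence <- function(model, patches) {
  UseMethod("predict_confidence")
}

#' @export
predict_confidence.kernel_classifier <- function(model, patches) {
  if (!model$trained) {
    stop("model is untrained; call `train_classifier()` first", call. = FALSE)
  }
  X <- as_patch_matrix(patches)
  as.numeric(sigmoid(cnn_predict(model$net, X)))
}

#' @export
predict.kernel_classifier <- function(object, newdata, ...) {
  predict_confidence(object, newdata)
}

# ---------------------------------------------------------------------------
# HOG + SVM baseline

#' Histogram-of-oriented-gradients descriptor of a 32x32 patch
#'
#' Unsigned gradient orientations (0-180 degrees) are soft-binned into 9
#' histogram bins over 4x4-pixel cells; blocks of 2x2 cells with a one-cell
#' stride are L2-normalized and concatenated, giving a descriptor of length
#' `((32/4 - 2) + 1)^2 * 4 * 9 = 1764`.
#'
#' @param gray 32x32 numeric matrix (grayscale patch; RGB arrays are converted
#'   with luminance weights).
#' @param cell Cell side in pixels.
#' @param block Block side in cells.
#' @param bins Number of orientation bins.
#'
#' @return Numeric descriptor vector.
#' @export
hog_descriptor <- function(gray, cell = 4L, block = 2L, bins = 9L) {
  if (length(dim(gray)) == 3L) {
    gray <- 0.299 * gray[, , 1] + 0.587 * gray[, , 2] + 0.114 * gray[, , 3]
  }
  H <- nrow(gray); W <- ncol(gray)
  stopifnot(H %% cell == 0L, W %% cell == 0L)
  # centered differences with replicated borders
  gx <- cbind(gray[, 2] - gray[, 1],
              (gray[, 3:W] - gray[, 1:(W - 2)]) / 2,
              gray[, W] - gray[, W - 1])
  gy <- rbind(gray[2, ] - gray[1, ],
              (gray[3:H, ] - gray[1:(H - 2), ]) / 2,
              gray[H, ] - gray[H - 1, ])
  mag <- sqrt(gx^2 + gy^2)
  ang <- (atan2(gy, gx) * 180 / pi) %% 180
  # soft assignment to the two neighboring orientation bins
  bw <- 180 / bins
  b0 <- floor(ang / bw - 0.5)
  frac <- ang / bw - 0.5 - b0
  b0 <- b0 %% bins
  b1 <- (b0 + 1) %% bins
  cy <- (seq_len(H) - 1L) %/% cell
  cx <- (seq_len(W) - 1L) %/% cell
  ncy <- H %/% cell; ncx <- W %/% cell
  hist_c <- array(0, c(ncy, ncx, bins))
  cell_idx <- outer(cy, cx * ncy, "+") + 1L         # ncy*ncx cell ids
  for (b in 0:(bins - 1L)) {
    w0 <- mag * (1 - frac) * (b0 == b)
    w1 <- mag * frac * (b1 == b)
    acc <- tapply(w0 + w1, cell_idx, sum)
    hist_c[, , b + 1L] <- matrix(as.numeric(acc), ncy, ncx)
  }
  nb_y <- ncy - block + 1L; nb_x <- ncx - block + 1L
  out <- numeric(nb_y * nb_x * block * block * bins)
  k <- 0L
  for (bx in seq_len(nb_x)) {
    for (by in seq_len(nb_y)) {
      v <- as.numeric(hist_c[by:(by + block - 1L), bx:(bx + block - 1L), ])
      nrm <- sqrt(sum(v^2) + 1e-12)
      out[(k + 1L):(k + length(v))] <- v / nrm
      k <- k + length(v)
    }
  }
  out
}

#' Train the HOG+SVM baseline classifier
#'
#' Extracts HOG descriptors (4x4-pixel cells, 2x2-cell blocks, 9 orientation
#' bins) from grayscale-converted patches and fits a linear-kernel
#' maximum-margin classifier. The descriptor length for a 32x32 patch (1764)
#' is asserted at build time.
#'
#' @param train A [patch_dataset()] containing both classes.
#' @param cost SVM regularization strength.
#'
#' @return Object of class `hog_svm`, exposing the same
#'   [predict_confidence()] interface as the CNN.
#' @export
hog_svm_classifier <- function(train, cost = 1) {
  stopifnot(inherits(train, "patch_dataset"))
  counts <- patch_label_counts(train)
  if (any(counts == 0L)) {
    stop("training set must contain both kernel and non_kernel patches",
         call. = FALSE)
  }
  feats <- hog_features(train)
  stopifnot(ncol(feats) == 1764L)
  labs <- factor(vapply(train$patches, `[[`, character(1), "label"),
                 levels = c("non_kernel", "kernel"))
  fit <- e1071::svm(x = feats, y = labs, kernel = "linear", cost = cost,
                    scale = FALSE)
  structure(list(svm = fit, cost = cost, descriptor_length = 1764L,
                 trained = TRUE),
            class = "hog_svm")
}

hog_features <- function(patches) {
  if (inherits(patches, "patch_dataset")) patches <- patches$patches
  t(vapply(patches, function(p) hog_descriptor(p$pixels / 255),
           numeric(1764L)))
}

#' @export
print.hog_svm <- function(x, ...) {
  cat(sprintf("HOG+SVM baseline: linear kernel, cost %g, %d support vectors\n",
              x$cost, x$svm$tot.nSV))
  invisible(x)
}

#' @export
predict_confidence.hog_svm <- function(model, patches) {
  if (inherits(patches, "kernel_patch")) patches <- list(patches)
  if (is.array(patches) && length(dim(patches)) == 3L) {
    patches <- list(patch(clamp_u8(patches), "non_kernel"))
  }
  feats <- hog_features(patches)
  dvm <- attr(predict(model$svm, feats, decision.values = TRUE),
              "decision.values")
  dv <- dvm[, 1]
  # orient so the kernel class gets high confidence
  if (startsWith(colnames(dvm)[1], "non_kernel")) dv <- -dv
  as.numeric(sigmoid(dv))
}

#' @export
predict.hog_svm <- function(object, newdata, ...) {
  predict_confidence(object, newdata)
}

# ---------------------------------------------------------------------------
# Metrics

#' Confusion-derived classification metrics
#'
#' False positives count predicted-kernel/labelled-non-kernel cases; false
#' negatives the reverse. Accuracy is `(n - fp - fn) / n` and the F-score is
#' the harmonic mean of precision and recall on the kernel class.
#'
#' @param labels,predictions Binary vectors (0/1, logical, or
#'   `"kernel"`/`"non_kernel"` characters) of equal length; 1 = kernel.
#'
#' @return Object of class `classification_metrics` with fields `fp`, `fn`,
#'   `accuracy`, `f_score`, `n`; printed to 3 decimals.
#' @export
#' @examples
#' m <- classification_metrics(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' m$accuracy
classification_metrics <- function(labels, predictions) {
  to01 <- function(v) {
    if (is.character(v)) as.numeric(v == "kernel")
    else if (is.factor(v)) as.numeric(v == "kernel")
    else as.numeric(v != 0)
  }
  y <- to01(labels); p <- to01(predictions)
  if (length(y) != length(p)) {
    stop("`labels` and `predictions` must have equal length", call. = FALSE)
  }
  n <- length(y)
  if (n < 1L) stop("need at least one observation", call. = FALSE)
  fp <- sum(p == 1 & y == 0)
  fn <- sum(p == 0 & y == 1)
  tp <- sum(p == 1 & y == 1)
  accuracy <- (n - fp - fn) / n
  if (tp + fp + fn == 0) {
    warning("no predicted and no actual positives; F-score defined as 0")
    f <- 0
  } else {
    f <- 2 * tp / (2 * tp + fp + fn)
  }
  structure(list(fp = as.integer(fp), fn = as.integer(fn), accuracy = accuracy,
                 f_score = f, n = as.integer(n)),
            class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf("n = %d: FP %d, FN %d, accuracy %.3f, F-score %.3f\n",
              x$n, x$fp, x$fn, x$accuracy, x$f_score))
  invisible(x)
}
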