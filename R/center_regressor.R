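# The kernel-center regression CNN: maps a 32x32 kernel patch to the (x, y)
# coordinates of the kernel center, trained with the smooth-L1 loss. The
# network predicts centers in normalized patch units [0, 1]^2 (kept O(1) for
# stable optimization); the pixel scale is restored at the interface.

#' Training configuration for the center regressor
#'
#' Defaults follow the reference protocol: mini-batch 45, 25,000 iterations,
#' learning rate 3e-4 (0.03%), Adam on the smooth-L1 loss, Xavier
#' initialization.
#'
#' @param batch_size Mini-batch size (>= 1).
#' @param total_iterations Number of mini-batch updates.
#' @param lr Adam learning rate (> 0).
#' @param eval_interval Iterations between test-loss evaluations.
#' @param rng_seed Seed covering initialization and batch sampling.
#'
#' @return Object of class `regressor_config`.
#' @export
regressor_config <- function(batch_size = 45L, total_iterations = 25000L,
                             lr = 3e-4, eval_interval = 100L, rng_seed = 1L) {
  stopifnot_scalar(batch_size, "batch_size", lower = 1)
  stopifnot_scalar(total_iterations, "total_iterations", lower = 1)
  stopifnot_scalar(lr, "lr", lower = 1e-12)
  stopifnot_scalar(eval_interval, "eval_interval", lower = 1)
  stopifnot_scalar(rng_seed, "rng_seed")
  structure(list(batch_size = as.integer(batch_size),
                 total_iterations = as.integer(total_iterations),
                 lr = lr, eval_interval = as.integer(eval_interval),
                 rng_seed = as.integer(rng_seed)),
            class = "regressor_config")
}

regressor_specs <- function() {
  list(conv_spec(32), relu_spec(),
       conv_spec(32), relu_spec(),
       maxpool_spec(2L, 2L), relu_spec(),
       conv_spec(64), relu_spec(),
       conv_spec(64), relu_spec(),
       conv_spec(64), relu_spec(),
       maxpool_spec(2L, 2L), relu_spec(),
       fc_spec(100L), relu_spec(),
       fc_spec(50L), relu_spec(),
       fc_spec(10L), relu_spec(),
       fc_spec(2L))
}

#' Build the (untrained) kernel-center regression CNN
#'
#' Architecture on a 32x32x3 input: two 3x3/32 convolutions (30x30x32,
#' 28x28x32), 2x2 max pool stride 2 (14x14x32), three 3x3/64 convolutions
#' (12x12x64, 10x10x64, 8x8x64), 2x2 max pool stride 2 (4x4x64), then fully
#' connected layers of 100, 50, 10 and 2 units. ReLU follows every layer
#' except the final linear pair of outputs; no batch normalization, no
#' dropout.
#'
#' @param rng_seed Seed for the weight initialization.
#' @return Object of class `center_regressor` (untrained).
#' @export
build_cnn_regressor <- function(rng_seed = 1L) {
  net <- with_seed(rng_seed, new_cnn(regressor_specs(), c(32L, 32L, 3L),
                                     out_activation = "linear"))
  structure(list(net = net, trained = FALSE, history = NULL, config = NULL,
                 rng_seed = as.integer(rng_seed)),
            class = "center_regressor")
}

#' Smooth-L1 loss between predicted and target coordinates
#'
#' Per coordinate, `f(d) = 0.5 d^2` for `|d| < 1` and `|d| - 0.5` otherwise,
#' summed over the two coordinates -- quadratic near zero, linear in the
#' tails, hence less outlier-sensitive than squared error, and continuous
#' with continuous first derivative at `|d| = 1`.
#'
#' @param predicted,target Numeric `(x, y)` pairs (or `2 x n` matrices, in
#'   which case the mean per-pair loss is returned).
#'
#' @return Non-negative scalar.
#' @export
#' @examples
#' smooth_l1_loss(c(0.5, 0), c(0, 0))   # 0.125
#' smooth_l1_loss(c(2, -1), c(0, 0))    # 2
smooth_l1_loss <- function(predicted, target) {
  if (any(!is.finite(predicted)) || any(!is.finite(target))) {
    stop("inputs to the smooth-L1 loss must be finite", call. = FALSE)
  }
  d <- abs(as.numeric(predicted) - as.numeric(target))
  v <- ifelse(d < 1, 0.5 * d^2, d - 0.5)
  if (is.matrix(predicted) && ncol(predicted) > 1L) {
    mean(colSums(matrix(v, nrow = nrow(predicted))))
  } else {
    sum(v)
  }
}

# gradient of the per-coordinate smooth-L1 wrt the prediction
smooth_l1_grad <- function(d) {
  ifelse(abs(d) < 1, d, sign(d))
}

#' Train the kernel-center regression CNN
#'
#' Minimizes the smooth-L1 loss between predicted and annotated centers
#' (both in normalized patch units) with Adam; deterministic for a fixed
#' config seed. Every training patch must carry a center annotation.
#'
#' @param train,test [patch_dataset()]s of kernel patches with centers.
#' @param config A [regressor_config()].
#'
#' @return A trained `center_regressor` with loss history (`$history`).
#' @export
train_regressor <- function(train, test = NULL, config = regressor_config()) {
  stopifnot(inherits(train, "patch_dataset"), inherits(config, "regressor_config"))
  tr <- patches_to_matrix(train)
  if (anyNA(tr$centers)) {
    stop("every training patch must carry a kernel center", call. = FALSE)
  }
  te <- if (!is.null(test)) patches_to_matrix(test)
  if (!is.null(te) && anyNA(te$centers)) {
    stop("every test patch must carry a kernel center", call. = FALSE)
  }
  head_sl1 <- function(z, t) {
    d <- z - t
    list(loss = smooth_l1_loss(z, t),
         dZ = smooth_l1_grad(d) / ncol(z))
  }
  with_seed(config$rng_seed, {
    net <- new_cnn(regressor_specs(), c(32L, 32L, 3L), "linear")
    fit <- run_training(net, tr$X, tr$centers / PATCH_SIZE,
                        te$X, if (!is.null(te)) te$centers / PATCH_SIZE,
                        config$total_iterations, config$batch_size,
                        list(initial = config$lr, reduced = NULL,
                             patience = Inf, tol = 0),
                        config$eval_interval, head_sl1)
    structure(list(net = fit$net, trained = TRUE, history = fit$history,
                   config = config, rng_seed = config$rng_seed),
              class = "center_regressor")
  })
}

#' @export
print.center_regressor <- function(x, ...) {
  cat("Kernel-center regression CNN (32x32x3 -> (x, y))\n")
  if (x$trained) {
    h <- x$history
    cat(sprintf("  trained %d iterations; final train loss %.5f (normalized units)\n",
                max(h$iteration), h$train_loss[nrow(h)]))
  } else {
    cat("  untrained\n")
  }
  invisible(x)
}

#' @export
plot.center_regressor <- function(x, ...) {
  h <- x$history
  if (is.null(h)) stop("no training history to plot", call. = FALSE)
  graphics::matplot(h$iteration, cbind(h$train_loss, h$test_loss), type = "l",
                    lty = 1, col = c("black", "red"), xlab = "iteration",
                    ylab = "smooth-L1 loss", ...)
  graphics::legend("topright", c("train", "test"), lty = 1,
                   col = c("black", "red"), bty = "n")
  invisible(x)
}

#' Predict the kernel center of a patch
#'
#' Inference is deterministic; predictions are clamped into the patch,
#' `[0, 32)` per coordinate.
#'
#' @param model A trained `center_regressor`.
#' @param patches A [patch()], 32x32x3 array, list of patches, or
#'   [patch_dataset()].
#'
#' @return For one patch, a `center_prediction` (list with `patch_xy`); for
#'   several, a list of them.
#' @export
predict_center <- function(model, patches) {
  stopifnot(inherits(model, "center_regressor"))
  if (!model$trained) {
    stop("model is untrained; call `train_regressor()` first", call. = FALSE)
  }
  X <- as_patch_matrix(patches)
  out <- cnn_predict(model$net, X) * PATCH_SIZE
  out <- pmin(pmax(out, 0), PATCH_SIZE - 1e-9)
  preds <- lapply(seq_len(ncol(out)), function(i) {
    structure(list(patch_xy = c(x = out[1, i], y = out[2, i]),
                   image_xy = NULL),
              class = "center_prediction")
  })
  if (length(preds) == 1L) preds[[1]] else preds
}

#' @export
predict.center_regressor <- function(object, newdata, ...) {
  predict_center(object, newdata)
}

#' @export
print.center_prediction <- function(x, ...) {
  cat(sprintf("patch center (%.2f, %.2f)", x$patch_xy[1], x$patch_xy[2]))
  if (!is.null(x$image_xy)) {
    cat(sprintf(" -> image (%.2f, %.2f)", x$image_xy[1], x$image_xy[2]))
  }
  cat("\n")
  invisible(x)
}

#' Map a patch-coordinate center prediction into image coordinates
#'
#' Inverts the window-to-patch rescale used at scoring time: a window of
#' `width x height` pixels was resampled to the 32x32 classifier/regressor
#' input, so `x_img = window_x + patch_x * width / 32` (and likewise for y).
#'
#' @param prediction A `center_prediction` (or numeric `(x, y)` in patch
#'   coordinates).
#' @param window The scored window: a list or one-row data.frame with `x`,
#'   `y`, `width`, `height`.
#'
#' @return Numeric `(x, y)` in image coordinates (inside the window); if
#'   `prediction` is a `center_prediction`, it is returned with `image_xy`
#'   filled in and the coordinates are accessible as `$image_xy`.
#' @export
#' @examples
#' center_to_image_coords(c(16, 16), list(x = 100, y = 50, width = 22, height = 32))
center_to_image_coords <- function(prediction, window) {
  p <- if (inherits(prediction, "center_prediction")) prediction$patch_xy
       else as.numeric(prediction)
  xy <- c(x = window$x + p[1] * window$width / PATCH_SIZE,
          y = window$y + p[2] * window$height / PATCH_SIZE)
  if (inherits(prediction, "center_prediction")) {
    prediction$image_xy <- xy
    prediction
  } else {
    xy
  }
}
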