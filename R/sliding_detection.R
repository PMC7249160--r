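# Sliding-window detection: enumerate window origins over the image, score
# every 32x22 crop with the patch classifier (rescaled to its 32x32 input),
# threshold on confidence, and prune overlaps with greedy non-maximum
# suppression.

#' Sliding-window / NMS configuration
#'
#' @param overlap_threshold NMS overlap threshold (lambda) in `[0, 1]`: after
#'   selecting the highest-confidence box, remaining boxes with IOU strictly
#'   greater than lambda are removed. Counts are sensitive to this value.
#' @param confidence_threshold Minimum classifier confidence for a window to
#'   enter NMS.
#' @param stride Scan stride `c(sy, sx)` in pixels.
#' @param window Window size `c(height, width)` in pixels; the reference
#'   pipeline uses 32x22 (kernels on an ear are taller than wide), rescaled
#'   to the classifier's square 32x32 input.
#'
#' @return Object of class `nms_config`.
#' @export
nms_config <- function(overlap_threshold = 0.3, confidence_threshold = 0.5,
                       stride = c(4L, 4L), window = c(32L, 22L)) {
  stopifnot_scalar(overlap_threshold, "overlap_threshold", 0, 1)
  stopifnot_scalar(confidence_threshold, "confidence_threshold", 0, 1)
  if (length(stride) == 1L) stride <- rep(stride, 2L)
  if (!is.numeric(stride) || length(stride) != 2L || any(stride < 1)) {
    stop("`stride` must be c(sy, sx) with both >= 1", call. = FALSE)
  }
  if (!is.numeric(window) || length(window) != 2L || any(window < 1)) {
    stop("`window` must be c(height, width)", call. = FALSE)
  }
  structure(list(overlap_threshold = overlap_threshold,
                 confidence_threshold = confidence_threshold,
                 stride = as.integer(stride), window = as.integer(window)),
            class = "nms_config")
}

#' Enumerate sliding-window origins
#'
#' Origins `(x, y) = (j * sx, i * sy)` for every placement of the full window
#' inside the image -- no partial border windows -- in row-major order (rows
#' outer, columns inner).
#'
#' @param image_size `c(H, W)` in pixels.
#' @param window `c(h, w)` window size.
#' @param stride `c(sy, sx)` stride.
#'
#' @return Matrix with columns `x`, `y` (0-based origins); zero rows when the
#'   window does not fit.
#' @export
#' @examples
#' nrow(enumerate_windows(c(64, 44), c(32, 22), c(4, 4)))  # 54
enumerate_windows <- function(image_size, window, stride) {
  H <- image_size[1]; W <- image_size[2]
  h <- window[1]; w <- window[2]
  sy <- stride[1]; sx <- stride[2]
  stopifnot(sy >= 1, sx >= 1)
  if (h > H || w > W) {
    return(matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("x", "y"))))
  }
  ys <- seq(0L, H - h, by = sy)
  xs <- seq(0L, W - w, by = sx)
  cbind(x = rep(xs, times = length(ys)), y = rep(ys, each = length(xs)))
}

# Gather-and-resample all windows of one size into the 3072 x N patch matrix
# in one vectorized pass: the bilinear taps are identical for every window,
# only the linear offset of the window origin differs.
windows_to_matrix <- function(pixels, origins, h, w) {
  H <- dim(pixels)[1]; W <- dim(pixels)[2]
  v <- as.numeric(pixels) / 255
  # destination pixel (i, j) of the 32x32 patch samples the window at
  # ((i + 0.5) h / 32 - 0.5, (j + 0.5) w / 32 - 0.5)
  sy <- pmin(pmax((seq_len(PATCH_SIZE) - 0.5) * h / PATCH_SIZE - 0.5, 0), h - 1)
  sx <- pmin(pmax((seq_len(PATCH_SIZE) - 0.5) * w / PATCH_SIZE - 0.5, 0), w - 1)
  y0 <- pmin(floor(sy), h - 2); fy <- sy - y0
  x0 <- pmin(floor(sx), w - 2); fx <- sx - x0
  FY <- rep(fy, times = PATCH_SIZE); FX <- rep(fx, each = PATCH_SIZE)
  Y0 <- rep(y0, times = PATCH_SIZE); X0 <- rep(x0, each = PATCH_SIZE)
  wts <- list((1 - FY) * (1 - FX), FY * (1 - FX), (1 - FY) * FX, FY * FX)
  offs <- list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  base <- as.numeric(origins[, "y"]) + H * as.numeric(origins[, "x"])
  chan <- H * W * (0:2)
  rel0 <- rep(Y0 + H * X0, times = 3L) + rep(chan, each = PATCH_SIZE^2)
  out <- matrix(0, PATCH_SIZE^2 * 3L, nrow(origins))
  wts3 <- lapply(wts, rep, times = 3L)
  for (t in 1:4) {
    rel <- rel0 + offs[[t]][1] + H * offs[[t]][2]
    out <- out + wts3[[t]] * matrix(v[outer(rel, base, "+") + 1], nrow = length(rel))
  }
  out
}

#' Score all sliding windows of an image with the patch classifier
#'
#' Each window crop is bilinearly rescaled to the classifier's 32x32 input
#' and scored in inference mode; windows below the confidence threshold are
#' dropped. Returned boxes keep their original 32x22 geometry.
#'
#' @param model A trained `kernel_classifier`.
#' @param image An [annotated_image()] or `H x W x 3` array.
#' @param config An [nms_config()].
#' @param chunk Windows scored per batch (memory/speed trade-off).
#'
#' @return Data frame of scored boxes: `x`, `y`, `width`, `height`,
#'   `confidence`.
#' @export
score_windows <- function(model, image, config = nms_config(), chunk = 1024L) {
  if (inherits(model, "kernel_classifier") && !model$trained) {
    stop("classifier is untrained", call. = FALSE)
  }
  pixels <- if (inherits(image, "annotated_image")) image$pixels else image
  H <- dim(pixels)[1]; W <- dim(pixels)[2]
  h <- config$window[1]; w <- config$window[2]
  origins <- enumerate_windows(c(H, W), config$window, config$stride)
  n <- nrow(origins)
  if (n == 0L) {
    return(data.frame(x = numeric(0), y = numeric(0), width = numeric(0),
                      height = numeric(0), confidence = numeric(0)))
  }
  conf <- numeric(n)
  i <- 0L
  while (i < n) {
    j <- min(i + chunk, n)
    X <- windows_to_matrix(pixels, origins[(i + 1):j, , drop = FALSE], h, w)
    conf[(i + 1):j] <- predict_confidence(model, X)
    i <- j
  }
  df <- data.frame(x = origins[, "x"], y = origins[, "y"],
                   width = w, height = h, confidence = conf)
  out <- df[conf >= config$confidence_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intersection over union of two axis-aligned boxes
#'
#' Boxes are half-open, `[x, x + w) x [y, y + h)`, on continuous coordinates;
#' the result is symmetric and lies in `[0, 1]`.
#'
#' @param a,b Boxes: numeric `(x, y, width, height)` vectors, or lists/one-row
#'   data frames with those fields.
#'
#' @return Scalar IOU.
#' @export
#' @examples
#' iou(c(0, 0, 2, 2), c(1, 1, 2, 2))  # 1/7
iou <- function(a, b) {
  a <- as_box(a); b <- as_box(b)
  if (a[3] <= 0 || a[4] <= 0 || b[3] <= 0 || b[4] <= 0) {
    stop("boxes must have positive area", call. = FALSE)
  }
  ix <- min(a[1] + a[3], b[1] + b[3]) - max(a[1], b[1])
  iy <- min(a[2] + a[4], b[2] + b[4]) - max(a[2], b[2])
  inter <- max(0, ix) * max(0, iy)
  union <- a[3] * a[4] + b[3] * b[4] - inter
  inter / union
}

as_box <- function(b) {
  if (is.list(b) || is.data.frame(b)) {
    as.numeric(c(b$x, b$y, b$width, b$height))
  } else {
    as.numeric(b)[1:4]
  }
}

# vectorized IOU of one box against a matrix of boxes (x, y, w, h columns)
iou_one_vs_many <- function(box, boxes) {
  ix <- pmin(box[1] + box[3], boxes[, 1] + boxes[, 3]) - pmax(box[1], boxes[, 1])
  iy <- pmin(box[2] + box[4], boxes[, 2] + boxes[, 4]) - pmax(box[2], boxes[, 2])
  inter <- pmax(0, ix) * pmax(0, iy)
  inter / (box[3] * box[4] + boxes[, 3] * boxes[, 4] - inter)
}

#' Greedy non-maximum suppression
#'
#' Repeatedly selects the highest-confidence box into the kept set and
#' removes every remaining box whose IOU with it is strictly greater than
#' `lambda` (boxes at exactly `lambda` survive). Ties on confidence break by
#' smaller `(y, x)` origin and then input order, so the output does not
#' depend on the input ordering.
#'
#' @param boxes Data frame of scored boxes (`x`, `y`, `width`, `height`,
#'   `confidence`).
#' @param lambda Overlap threshold in `[0, 1]`.
#'
#' @return The kept boxes in selection order (confidences non-increasing).
#' @export
nms <- function(boxes, lambda = 0.3) {
  stopifnot_scalar(lambda, "lambda", 0, 1)
  if (is.null(boxes) || nrow(boxes) == 0L) return(boxes)
  ord <- order(-boxes$confidence, boxes$y, boxes$x, seq_len(nrow(boxes)))
  b <- boxes[ord, , drop = FALSE]
  m <- cbind(b$x, b$y, b$width, b$height)
  n <- nrow(b)
  alive <- rep(TRUE, n)
  keep <- integer(0)
  for (i in seq_len(n)) {
    if (!alive[i]) next
    keep <- c(keep, i)
    alive[i] <- FALSE
    rest <- which(alive)
    if (length(rest) == 0L) break
    ious <- iou_one_vs_many(m[i, ], m[rest, , drop = FALSE])
    alive[rest[ious > lambda]] <- FALSE
  }
  out <- b[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
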