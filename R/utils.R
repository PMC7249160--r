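# Shared internal helpers: seeded evaluation, rounding, image resampling and
# color manipulation. Coordinate convention throughout the package: x = column,
# y = row, 0-based, origin at the top-left corner, and pixel (r, c) covers the
# half-open square [c, c + 1) x [r, r + 1). A point is therefore "inside" pixel
# (r, c) when floor(x) == c and floor(y) == r.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive k reproducible sub-seeds (< 2^31) from one master seed.
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

# Round half away from zero: 252.5 -> 253, -2.5 -> -3. Distinct from base R's
# round(), which rounds half to even.
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

stopifnot_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single finite number in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}

stopifnot_range <- function(x, name, lower = -Inf) {
  if (!is.numeric(x) || length(x) != 2L || any(!is.finite(x)) ||
      x[1] > x[2] || x[1] < lower) {
    stop(sprintf("`%s` must be a numeric range c(low, high) with low <= high and low >= %s",
                 name, format(lower)), call. = FALSE)
  }
  invisible(x)
}

runif_range <- function(range, n = 1L) {
  if (range[1] == range[2]) rep(range[1], n) else runif(n, range[1], range[2])
}

sample_int_range <- function(range, n = 1L) {
  lo <- as.integer(ceiling(range[1])); hi <- as.integer(floor(range[2]))
  if (lo >= hi) rep(lo, n) else lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

# Bilinear resampling of an H x W (x C) numeric array to out_h x out_w.
# Output pixel (i, j) (0-based) samples the source at
# ((i + 0.5) * H / out_h - 0.5, (j + 0.5) * W / out_w - 0.5) in pixel-center
# coordinates, clamped to the source grid. This is the single resampler used
# for patch rescaling and window scoring, so the forward coordinate map
# `p' = (p - origin) * out / size` is its exact geometric counterpart.
bilinear_resize <- function(img, out_h, out_w) {
  d <- dim(img)
  H <- d[1]; W <- d[2]
  nc <- if (length(d) == 3L) d[3] else 1L
  sy <- pmin(pmax((seq_len(out_h) - 0.5) * H / out_h - 0.5, 0), H - 1)
  sx <- pmin(pmax((seq_len(out_w) - 0.5) * W / out_w - 0.5, 0), W - 1)
  y0 <- pmin(floor(sy), H - 2); x0 <- pmin(floor(sx), W - 2)
  if (H == 1L) y0 <- rep(0, out_h)
  if (W == 1L) x0 <- rep(0, out_w)
  fy <- sy - y0; fx <- sx - x0
  i0 <- y0 + 1L; i1 <- pmin(y0 + 2L, H); j0 <- x0 + 1L; j1 <- pmin(x0 + 2L, W)
  wy0 <- matrix(1 - fy, out_h, out_w); wx0 <- matrix(1 - fx, out_h, out_w, byrow = TRUE)
  out <- array(0, c(out_h, out_w, nc))
  im <- if (length(d) == 3L) img else array(img, c(H, W, 1L))
  for (c in seq_len(nc)) {
    ch <- im[, , c]
    out[, , c] <- ch[i0, j0] * wy0 * wx0 +
      ch[i1, j0] * (1 - wy0) * wx0 +
      ch[i0, j1] * wy0 * (1 - wx0) +
      ch[i1, j1] * (1 - wy0) * (1 - wx0)
  }
  if (length(d) == 3L) out else out[, , 1L]
}

# Integer-aligned crop of an image array, clamped by shifting the window back
# inside the bounds (never by shrinking it). Returns NULL if the window is
# larger than the image. x, y are 0-based column/row origins.
crop_window <- function(pixels, x, y, w, h) {
  H <- dim(pixels)[1]; W <- dim(pixels)[2]
  if (w > W || h > H) return(NULL)
  x <- max(0L, min(as.integer(x), W - w))
  y <- max(0L, min(as.integer(y), H - h))
  list(pixels = pixels[(y + 1L):(y + h), (x + 1L):(x + w), , drop = FALSE],
       x = x, y = y, w = w, h = h)
}

# Multiplicative brightness/saturation scaling and additive hue rotation of an
# 8-bit RGB array. hue_shift is in degrees.
jitter_colors <- function(pixels, brightness = 1, saturation = 1, hue_shift = 0) {
  d <- dim(pixels)
  rgb <- rbind(as.numeric(pixels[, , 1]), as.numeric(pixels[, , 2]),
               as.numeric(pixels[, , 3]))
  hsv_m <- rgb2hsv(rgb, maxColorValue = 255)
  hsv_m[1, ] <- (hsv_m[1, ] + hue_shift / 360) %% 1
  hsv_m[2, ] <- pmin(1, pmax(0, hsv_m[2, ] * saturation))
  hsv_m[3, ] <- pmin(1, pmax(0, hsv_m[3, ] * brightness))
  cols <- col2rgb(hsv(hsv_m[1, ], hsv_m[2, ], hsv_m[3, ]))
  out <- array(0L, d)
  out[, , 1] <- as.integer(cols[1, ]); out[, , 2] <- as.integer(cols[2, ])
  out[, , 3] <- as.integer(cols[3, ])
  out
}

# Clamp a float image array to valid 8-bit integers.
clamp_u8 <- function(x) {
  storage.mode(x) <- "integer"
  x[x < 0L] <- 0L; x[x > 255L] <- 255L
  x
}

iso_timestamp <- function() format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")

log_msg <- function(...) {
  message(sprintf("[%s] %s", iso_timestamp(), sprintf(...)))
}
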