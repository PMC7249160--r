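# Procedural generator of annotated corn-ear scenes. The generator emulates
# the statistical structure of real ear photographs -- several hundred dense,
# near-touching kernels per ear, varied ear tilt, uncontrolled lighting, and
# soil/grass/hand-like backgrounds -- while providing exact ground truth: the
# sub-pixel center of every rendered kernel.
#
# Geometry. Kernels sit on a staggered lattice: columns of kernels with
# uniform horizontal spacing 2.2 * radius, rows spaced 2.4 * (1.3 * radius)
# vertically, alternate columns offset by half a row. Curvature of the ear is
# expressed through kernel appearance (horizontal compression and darkening
# toward the silhouette edges), not through center spacing, which keeps the
# minimum pairwise center distance bounded below by the kernel radius. The
# camera-facing lattice is modelled as 40% of the ear's kernel columns, so the
# whole-ear ground-truth count is 2.5x the visible count -- the same
# symmetric-ear premise that motivates the default extrapolation factor.

BACKGROUND_CLASSES <- c("soil", "grass", "hand", "plain")

resolve_background <- function(class) {
  if (class == "random") sample(BACKGROUND_CLASSES, 1L) else class
}

#' Parameters of a synthetic ear scene
#'
#' Bundles and validates every knob of the synthetic generator. All ranges are
#' `c(low, high)` and are sampled uniformly per ear (integer-valued for
#' counts).
#'
#' @param image_size Height and width of the scene in pixels, `c(H, W)`.
#'   The default follows the 768x1024 full-ear photograph size used as the
#'   working resolution for ear images.
#' @param n_ears Number of ears to place in the scene.
#' @param kernels_per_column Range of kernels per visible lattice column.
#' @param visible_columns Range of camera-facing kernel columns.
#' @param kernel_radius Range of the kernel half-width in pixels (the kernel
#'   ellipse is `1.3x` taller than wide). Must be at least 3 px.
#' @param ear_tilt Range of ear tilt in degrees (rotation in the image plane).
#' @param lighting_gain Range of a global multiplicative lighting factor;
#'   values below/above 1 emulate under-/over-exposure.
#' @param background_class One of `"soil"`, `"grass"`, `"hand"`, `"plain"`,
#'   or `"random"` to draw one of the four per scene.
#' @param jitter Standard deviation (px) of the kernel-position noise added to
#'   lattice positions; draws are clipped at 2.5 sigma so the lattice spacing
#'   guarantee survives jitter.
#' @param rng_seed Integer seed; identical parameters and seed give
#'   bit-identical scenes.
#'
#' @return An object of class `ear_scene_params`.
#' @seealso [render_ear_image()], [render_batch_scene()]
#' @export
#' @examples
#' p <- ear_scene_params(image_size = c(256, 192), kernel_radius = c(5, 6),
#'                       kernels_per_column = c(8, 10), visible_columns = c(5, 6))
#' img <- render_ear_image(p)
#' nrow(img$centers)
ear_scene_params <- function(image_size = c(1024, 768),
                             n_ears = 1L,
                             kernels_per_column = c(18, 24),
                             visible_columns = c(11, 13),
                             kernel_radius = c(9, 11),
                             ear_tilt = c(-10, 10),
                             lighting_gain = c(0.85, 1.15),
                             background_class = "soil",
                             jitter = 0.4,
                             rng_seed = 1L) {
  if (!is.numeric(image_size) || length(image_size) != 2L ||
      any(image_size < 64)) {
    stop("`image_size` must be c(H, W) with both dimensions >= 64 px",
         call. = FALSE)
  }
  stopifnot_scalar(n_ears, "n_ears", lower = 1)
  stopifnot_range(kernels_per_column, "kernels_per_column", lower = 1)
  stopifnot_range(visible_columns, "visible_columns", lower = 1)
  stopifnot_range(kernel_radius, "kernel_radius", lower = 3)
  stopifnot_range(ear_tilt, "ear_tilt")
  stopifnot_range(lighting_gain, "lighting_gain", lower = 0)
  background_class <- match.arg(background_class,
                                c(BACKGROUND_CLASSES, "random"))
  stopifnot_scalar(jitter, "jitter", lower = 0)
  stopifnot_scalar(rng_seed, "rng_seed")
  structure(list(image_size = as.integer(image_size),
                 n_ears = as.integer(n_ears),
                 kernels_per_column = kernels_per_column,
                 visible_columns = visible_columns,
                 kernel_radius = kernel_radius,
                 ear_tilt = ear_tilt,
                 lighting_gain = lighting_gain,
                 background_class = background_class,
                 jitter = jitter,
                 rng_seed = as.integer(rng_seed)),
            class = "ear_scene_params")
}

#' @export
print.ear_scene_params <- function(x, ...) {
  cat("Synthetic ear scene parameters\n")
  cat(sprintf("  image: %d x %d px, %d ear(s), background: %s\n",
              x$image_size[1], x$image_size[2], x$n_ears, x$background_class))
  cat(sprintf("  columns %g-%g, kernels/column %g-%g, radius %g-%g px\n",
              x$visible_columns[1], x$visible_columns[2],
              x$kernels_per_column[1], x$kernels_per_column[2],
              x$kernel_radius[1], x$kernel_radius[2]))
  cat(sprintf("  tilt %g to %g deg, gain %g-%g, jitter sd %g px, seed %d\n",
              x$ear_tilt[1], x$ear_tilt[2], x$lighting_gain[1],
              x$lighting_gain[2], x$jitter, x$rng_seed))
  invisible(x)
}

#' Annotated image container
#'
#' An RGB scene with ground-truth kernel centers, one axis-aligned box per
#' kernel, a per-kernel ear id, and the whole-ear ground-truth kernel count
#' (visible centers plus the hidden side implied by the generator's
#' symmetric-ear geometry).
#'
#' @param pixels `H x W x 3` integer array with 8-bit channels.
#' @param centers `n x 2` matrix of continuous (x, y) image coordinates.
#' @param boxes Optional `n x 4` matrix (x, y, width, height), one per center.
#' @param ear Optional integer vector assigning each center to an ear.
#' @param total_kernels Optional whole-scene ground-truth kernel count.
#'
#' @return An object of class `annotated_image`.
#' @export
annotated_image <- function(pixels, centers, boxes = NULL, ear = NULL,
                            total_kernels = NULL) {
  stopifnot(length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  centers <- matrix(as.numeric(centers), ncol = 2L,
                    dimnames = list(NULL, c("x", "y")))
  H <- dim(pixels)[1]; W <- dim(pixels)[2]
  if (nrow(centers) > 0 &&
      (any(centers[, 1] < 0) || any(centers[, 1] >= W) ||
       any(centers[, 2] < 0) || any(centers[, 2] >= H))) {
    stop("every center must lie inside the image bounds", call. = FALSE)
  }
  if (!is.null(boxes)) {
    boxes <- matrix(as.numeric(boxes), ncol = 4L,
                    dimnames = list(NULL, c("x", "y", "width", "height")))
    if (nrow(boxes) != nrow(centers)) {
      stop("`boxes` must have one row per center", call. = FALSE)
    }
    inside <- centers[, 1] >= boxes[, 1] &
      centers[, 1] < boxes[, 1] + boxes[, 3] &
      centers[, 2] >= boxes[, 2] &
      centers[, 2] < boxes[, 2] + boxes[, 4]
    if (nrow(boxes) > 0 && !all(inside)) {
      stop("each center must lie inside its box", call. = FALSE)
    }
  }
  structure(list(pixels = clamp_u8(pixels), centers = centers, boxes = boxes,
                 ear = ear, total_kernels = total_kernels),
            class = "annotated_image")
}

#' @export
print.annotated_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("Annotated image: %d x %d px, %d kernel center(s)",
              d[1], d[2], nrow(x$centers)))
  if (!is.null(x$ear)) cat(sprintf(", %d ear(s)", length(unique(x$ear))))
  if (!is.null(x$total_kernels)) {
    cat(sprintf(", whole-ear ground truth %d", x$total_kernels))
  }
  cat("\n")
  invisible(x)
}

# Sample the geometry of one ear: lattice centers in the ear's local frame
# (before tilt), per-kernel sizes/appearance, and the ear's rotated bounding
# half-extents.
sample_ear_geometry <- function(params) {
  r <- runif_range(params$kernel_radius)
  aspect <- 1.3
  ry <- aspect * r
  s_h <- 2.2 * r            # column spacing
  s_v <- 2.4 * ry           # row spacing within a column
  ncol_vis <- sample_int_range(params$visible_columns)
  rows <- sample_int_range(params$kernels_per_column)
  tilt <- runif_range(params$ear_tilt)
  n <- ncol_vis * rows
  j <- rep(seq_len(ncol_vis) - 1L, each = rows)
  i <- rep(seq_len(rows) - 1L, times = ncol_vis)
  x <- (j - (ncol_vis - 1) / 2) * s_h
  y <- (i - (rows - 1) / 2) * s_v + ifelse(j %% 2L == 1L, s_v / 2, 0) - s_v / 4
  if (params$jitter > 0) {
    clip <- 2.5 * params$jitter
    x <- x + pmin(pmax(rnorm(n, 0, params$jitter), -clip), clip)
    y <- y + pmin(pmax(rnorm(n, 0, params$jitter), -clip), clip)
  }
  # normalized horizontal position inside the ear, drives edge foreshortening
  half_w <- (ncol_vis - 1) / 2 * s_h + r
  xi <- if (half_w > 0) pmin(pmax(x / max(half_w, 1e-9), -1), 1) else rep(0, n)
  hue_jit <- runif(n, -8, 8)
  bright_jit <- runif(n, 0.92, 1.08)
  list(r = r, ry = ry, s_h = s_h, s_v = s_v, rows = rows, ncol_vis = ncol_vis,
       tilt = tilt, local_x = x, local_y = y, xi = xi,
       hue_jit = hue_jit, bright_jit = bright_jit,
       half_w = half_w,
       half_h = (rows - 1) / 2 * s_v + s_v / 4 + ry,
       total_kernels = as.integer(round(2.5 * ncol_vis) * rows))
}

# Rotated bounding half-extents of an ear (for placement / fit checks).
ear_half_extents <- function(geom) {
  th <- geom$tilt * pi / 180
  hw <- geom$half_w + 2; hh <- geom$half_h + 2 * geom$ry + 2
  c(w = abs(cos(th)) * hw + abs(sin(th)) * hh,
    h = abs(sin(th)) * hw + abs(cos(th)) * hh)
}

# Value-noise background tinted per class: a coarse uniform grid is bilinearly
# upsampled and modulates the class base color, plus fine per-pixel noise.
render_background <- function(H, W, class) {
  base <- switch(class,
                 soil  = c(118, 86, 54),
                 grass = c(72, 112, 48),
                 hand  = c(198, 158, 128),
                 plain = c(128, 128, 128))
  cell <- 16L
  gh <- max(2L, ceiling(H / cell)); gw <- max(2L, ceiling(W / cell))
  coarse <- matrix(runif(gh * gw, 0.55, 1.25), gh, gw)
  field <- bilinear_resize(coarse, H, W)
  fine <- matrix(runif(H * W, -8, 8), H, W)
  px <- array(0, c(H, W, 3))
  for (c in 1:3) px[, , c] <- base[c] * field + fine
  px
}

# Paint one ear (silhouette + kernels) onto `px` (float array), returning the
# updated array and the kernel centers/boxes in image coordinates.
paint_ear <- function(px, geom, cx, cy) {
  H <- dim(px)[1]; W <- dim(px)[2]
  th <- geom$tilt * pi / 180
  ct <- cos(th); st <- sin(th)
  # --- silhouette: capsule around the lattice in the ear frame
  ext <- ear_half_extents(geom)
  x0 <- max(0L, floor(cx - ext["w"])); x1 <- min(W - 1L, ceiling(cx + ext["w"]))
  y0 <- max(0L, floor(cy - ext["h"])); y1 <- min(H - 1L, ceiling(cy + ext["h"]))
  xs <- x0:x1; ys <- y0:y1
  gx <- matrix(xs + 0.5, length(ys), length(xs), byrow = TRUE) - cx
  gy <- matrix(ys + 0.5, length(ys), length(xs)) - cy
  u <- ct * gx + st * gy          # ear-frame horizontal
  v <- -st * gx + ct * gy         # ear-frame vertical
  # rounded-tip rectangle: straight sides span the whole lattice (so every
  # kernel center is inside by construction), elliptical tips beyond the ends
  hw <- geom$half_w + 1; hh <- geom$half_h + 1
  tip <- 2 * geom$ry
  dv <- pmax(abs(v) - hh, 0)
  inside <- (u / hw)^2 + (dv / tip)^2 <= 1
  if (any(inside)) {
    xi_pix <- pmin(pmax(u / hw, -1), 1)
    shade <- 0.55 + 0.45 * sqrt(pmax(0, 1 - xi_pix^2))
    cob <- c(146, 92, 62)
    for (c in 1:3) {
      ch <- px[ys + 1L, xs + 1L, c]
      ch[inside] <- (cob[c] * shade)[inside]
      px[ys + 1L, xs + 1L, c] <- ch
    }
  }
  # --- kernels
  n <- length(geom$local_x)
  centers <- matrix(0, n, 2)
  boxes <- matrix(0, n, 4)
  compress <- pmax(0.45, sqrt(pmax(0, 1 - 0.72 * geom$xi^2)))
  edge_shade <- 0.45 + 0.55 * sqrt(pmax(0, 1 - 0.8 * geom$xi^2))
  base_col <- c(232, 188, 64)
  for (k in seq_len(n)) {
    # center in image coordinates
    kx <- cx + ct * geom$local_x[k] - st * geom$local_y[k]
    ky <- cy + st * geom$local_x[k] + ct * geom$local_y[k]
    a <- geom$r * compress[k]     # half-width in the ear frame
    b <- geom$ry                  # half-height
    bb_w <- sqrt((a * ct)^2 + (b * st)^2)
    bb_h <- sqrt((a * st)^2 + (b * ct)^2)
    centers[k, ] <- c(kx, ky)
    boxes[k, ] <- c(kx - bb_w, ky - bb_h, 2 * bb_w, 2 * bb_h)
    kx0 <- max(0L, floor(kx - bb_w - 1)); kx1 <- min(W - 1L, ceiling(kx + bb_w + 1))
    ky0 <- max(0L, floor(ky - bb_h - 1)); ky1 <- min(H - 1L, ceiling(ky + bb_h + 1))
    if (kx0 > kx1 || ky0 > ky1) next
    kxs <- kx0:kx1; kys <- ky0:ky1
    dx <- matrix(kxs + 0.5, length(kys), length(kxs), byrow = TRUE) - kx
    dy <- matrix(kys + 0.5, length(kys), length(kxs)) - ky
    ku <- ct * dx + st * dy
    kv <- -st * dx + ct * dy
    rho2 <- (ku / a)^2 + (kv / b)^2
    ink <- rho2 <= 1
    if (!any(ink)) next
    # radial shading with an off-center highlight toward the upper-left
    shade <- edge_shade[k] * (0.55 + 0.45 * sqrt(pmax(0, 1 - rho2)))
    hl <- 0.30 * exp(-(((ku + 0.30 * a)^2 + (kv + 0.30 * b)^2) / (0.22 * a * b)))
    col <- kernel_color(base_col, geom$hue_jit[k], geom$bright_jit[k])
    for (c in 1:3) {
      ch <- px[kys + 1L, kxs + 1L, c]
      val <- col[c] * (shade + hl)
      ch[ink] <- pmin(255, val)[ink]
      px[kys + 1L, kxs + 1L, c] <- ch
    }
  }
  list(px = px, centers = centers, boxes = boxes)
}

# Per-kernel hue/brightness jitter around the base kernel yellow.
kernel_color <- function(base, hue_shift, brightness) {
  hsv_m <- rgb2hsv(matrix(base, 3, 1), maxColorValue = 255)
  h <- (hsv_m[1, 1] + hue_shift / 360) %% 1
  v <- pmin(1, hsv_m[3, 1] * brightness)
  as.numeric(col2rgb(hsv(h, hsv_m[2, 1], v)))
}

#' Render one synthetic annotated ear image
#'
#' Draws a single corn ear (shaded elliptical kernels packed on a staggered
#' lattice inside an ear silhouette, only the camera-facing side populated)
#' over a textured background, and returns the exact center of every rendered
#' kernel as ground truth. Deterministic for a fixed `rng_seed`.
#'
#' @param params An [ear_scene_params()] object (with `n_ears = 1`; use
#'   [render_batch_scene()] for multi-ear scenes).
#'
#' @return An [annotated_image()] with `centers`, per-kernel `boxes`, and
#'   `total_kernels`, the whole-ear ground-truth count implied by the
#'   generator's symmetric-ear geometry (the visible lattice is 40% of the
#'   ear's kernel columns). The realized `background` class and `tilt`
#'   (degrees) are recorded on the object.
#' @export
render_ear_image <- function(params) {
  stopifnot(inherits(params, "ear_scene_params"))
  with_seed(params$rng_seed, {
    H <- params$image_size[1]; W <- params$image_size[2]
    bg <- resolve_background(params$background_class)
    geom <- sample_ear_geometry(params)
    ext <- ear_half_extents(geom)
    if (2 * ext["w"] > W || 2 * ext["h"] > H) {
      stop(sprintf(paste0("image (%d x %d) is too small for an ear with ",
                          "radius %.1f px and %d x %d kernels; enlarge ",
                          "`image_size` or reduce `kernel_radius`"),
                   H, W, geom$r, geom$ncol_vis, geom$rows), call. = FALSE)
    }
    # small random offset of the ear center, kept inside the frame
    mx <- (W / 2 - ext["w"]); my <- (H / 2 - ext["h"])
    cx <- W / 2 + runif(1, -1, 1) * min(0.05 * W, mx)
    cy <- H / 2 + runif(1, -1, 1) * min(0.05 * H, my)
    px <- render_background(H, W, bg)
    ear <- paint_ear(px, geom, cx, cy)
    gain <- runif_range(params$lighting_gain)
    out <- annotated_image(clamp_u8(ear$px * gain), ear$centers, ear$boxes,
                           ear = rep(1L, nrow(ear$centers)),
                           total_kernels = geom$total_kernels)
    out$background <- bg
    out$tilt <- geom$tilt
    out
  })
}

#' Render a batch scene with several non-overlapping ears
#'
#' Places `n_ears >= 2` independently tilted ears in one image (bounded random
#' placement retries), pooling centers across ears; per-ear center lists are
#' recoverable through the `ear` id vector.
#'
#' @param params An [ear_scene_params()] object with `n_ears >= 2`.
#' @param max_tries Placement attempts per ear before giving up.
#'
#' @return An [annotated_image()]; `total_kernels` sums the per-ear whole-ear
#'   ground truths.
#' @export
render_batch_scene <- function(params, max_tries = 200L) {
  stopifnot(inherits(params, "ear_scene_params"))
  if (params$n_ears < 2L) {
    stop("`render_batch_scene()` needs n_ears >= 2; use `render_ear_image()`",
         call. = FALSE)
  }
  with_seed(params$rng_seed, {
    H <- params$image_size[1]; W <- params$image_size[2]
    bg <- resolve_background(params$background_class)
    px <- render_background(H, W, bg)
    placed <- list()   # per-ear (cx, cy, half extents)
    centers <- NULL; boxes <- NULL; ear_id <- integer(0)
    total <- 0L
    for (e in seq_len(params$n_ears)) {
      geom <- sample_ear_geometry(params)
      ext <- ear_half_extents(geom)
      if (2 * ext["w"] > W || 2 * ext["h"] > H) {
        stop("image too small to hold one of the requested ears", call. = FALSE)
      }
      ok <- FALSE
      for (t in seq_len(max_tries)) {
        cx <- runif(1, ext["w"], W - ext["w"])
        cy <- runif(1, ext["h"], H - ext["h"])
        clear <- TRUE
        for (p in placed) {
          if (abs(cx - p$cx) < ext["w"] + p$w + 4 &&
              abs(cy - p$cy) < ext["h"] + p$h + 4) { clear <- FALSE; break }
        }
        if (clear) { ok <- TRUE; break }
      }
      if (!ok) {
        stop(sprintf("could not place ear %d without overlap after %d tries",
                     e, max_tries), call. = FALSE)
      }
      res <- paint_ear(px, geom, cx, cy)
      px <- res$px
      placed[[e]] <- list(cx = cx, cy = cy, w = ext["w"], h = ext["h"])
      centers <- rbind(centers, res$centers)
      boxes <- rbind(boxes, res$boxes)
      ear_id <- c(ear_id, rep.int(e, nrow(res$centers)))
      total <- total + geom$total_kernels
    }
    gain <- runif_range(params$lighting_gain)
    out <- annotated_image(clamp_u8(px * gain), centers, boxes, ear = ear_id,
                           total_kernels = total)
    out$background <- bg
    out
  })
}
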