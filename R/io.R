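# Readers and writers for the artifacts the pipeline touches: PNG images,
# center annotations (CSV and LabelMe-style JSON point shapes), detection
# tables, overlays, patch datasets and model checkpoints. Readers validate
# and reject malformed inputs; they never silently repair them. Every writer
# leaves a JSON sidecar recording the configuration and seed that produced
# the artifact.

#' Read an image file into an 8-bit RGB array
#'
#' PNG is read natively. Grayscale images are replicated to three channels;
#' an alpha channel is dropped.
#'
#' @param path Path to a PNG file.
#' @return `H x W x 3` integer array (0-255).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path, call. = FALSE)
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] == 2L) {
    img <- array(rep(img[, , 1], 3L), c(dim(img)[1:2], 3L))
  }
  clamp_u8(round(img * 255))
}

#' Write an 8-bit RGB array as PNG
#'
#' @param pixels `H x W x 3` integer array (0-255) or [annotated_image()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_image <- function(pixels, path) {
  if (inherits(pixels, "annotated_image")) pixels <- pixels$pixels
  png::writePNG(pixels / 255, path)
  invisible(path)
}

#' Read per-image kernel-center annotations
#'
#' Two dialects are understood and produce identical structures for
#' equivalent content:
#' * `csv`: a table with header `image,x,y`, one row per center;
#' * `labelme_json`: a LabelMe-style JSON file with `imagePath` and point
#'   `shapes` (one point per kernel).
#'
#' Coordinates use the package convention: x = column, y = row, 0-based.
#'
#' @param path File path.
#' @param dialect `"csv"` or `"labelme_json"`.
#' @param image_size Optional `c(H, W)` used to validate that every center
#'   lies inside the image.
#'
#' @return Named list (one element per image) of `n x 2` matrices with
#'   columns `x`, `y`.
#' @export
read_annotations <- function(path, dialect = c("csv", "labelme_json"),
                             image_size = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such annotation file: ", path, call. = FALSE)
  out <- if (dialect == "csv") {
    df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                   error = function(e) {
                     stop("malformed annotation CSV '", path, "': ",
                          conditionMessage(e), call. = FALSE)
                   })
    if (nrow(df) == 0L && ncol(df) == 0L) {
      list()
    } else {
      if (!all(c("image", "x", "y") %in% names(df))) {
        stop("annotation CSV must have columns image,x,y", call. = FALSE)
      }
      bad <- which(!is.finite(df$x) | !is.finite(df$y))
      if (length(bad) > 0) {
        stop(sprintf("non-numeric center in '%s' at data row %d", path, bad[1]),
             call. = FALSE)
      }
      lapply(split(df[c("x", "y")], df$image), function(d) {
        cbind(x = d$x, y = d$y)
      })
    }
  } else {
    js <- tryCatch(jsonlite::read_json(path),
                   error = function(e) {
                     stop("malformed LabelMe JSON '", path, "': ",
                          conditionMessage(e), call. = FALSE)
                   })
    img <- js$imagePath
    if (is.null(img)) stop("LabelMe JSON lacks imagePath", call. = FALSE)
    pts <- lapply(js$shapes, function(s) {
      if (!identical(s$shape_type, "point")) return(NULL)
      p <- s$points[[1]]
      c(as.numeric(p[[1]]), as.numeric(p[[2]]))
    })
    pts <- Filter(Negate(is.null), pts)
    m <- if (length(pts)) do.call(rbind, pts) else matrix(numeric(0), ncol = 2L)
    colnames(m) <- c("x", "y")
    stats::setNames(list(m), img)
  }
  if (!is.null(image_size)) {
    H <- image_size[1]; W <- image_size[2]
    for (nm in names(out)) {
      m <- out[[nm]]
      if (nrow(m) > 0 && (any(m[, "x"] < 0) || any(m[, "x"] >= W) ||
                          any(m[, "y"] < 0) || any(m[, "y"] >= H))) {
        stop(sprintf("center outside the %d x %d image bounds in '%s' (%s)",
                     H, W, path, nm), call. = FALSE)
      }
    }
  }
  out
}

#' Write per-image kernel-center annotations
#'
#' @param centers_by_image Named list of `n x 2` center matrices (or one
#'   matrix, with `image` giving its name).
#' @param path Output file.
#' @param dialect `"csv"` (all images in one table) or `"labelme_json"` (one
#'   image per file).
#' @param image Image name when passing a single matrix.
#' @return The path, invisibly.
#' @export
write_annotations <- function(centers_by_image, path,
                              dialect = c("csv", "labelme_json"),
                              image = "image") {
  dialect <- match.arg(dialect)
  if (is.matrix(centers_by_image)) {
    centers_by_image <- stats::setNames(list(centers_by_image), image)
  }
  if (dialect == "csv") {
    rows <- lapply(names(centers_by_image), function(nm) {
      m <- centers_by_image[[nm]]
      if (nrow(m) == 0L) return(NULL)
      data.frame(image = nm, x = m[, 1], y = m[, 2])
    })
    df <- do.call(rbind, rows)
    if (is.null(df)) df <- data.frame(image = character(0), x = numeric(0),
                                      y = numeric(0))
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    if (length(centers_by_image) != 1L) {
      stop("LabelMe JSON holds one image per file", call. = FALSE)
    }
    nm <- names(centers_by_image)[1]
    m <- centers_by_image[[1]]
    shapes <- lapply(seq_len(nrow(m)), function(i) {
      list(label = "kernel", shape_type = "point",
           points = list(c(m[i, 1], m[i, 2])))
    })
    jsonlite::write_json(list(imagePath = nm, shapes = shapes), path,
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Burn detection boxes and center dots into a copy of an image
#'
#' Boxes are drawn as one-pixel blue borders and centers as blue dots
#' (radius 2 px), the conventional overlay for kernel-classified windows and
#' regressed centers. The source image is never mutated; with no detections
#' and no centers the output is pixel-identical to the input.
#'
#' @param image [annotated_image()] or `H x W x 3` array.
#' @param detections Data frame with `x`, `y`, `width`, `height` (optional).
#' @param centers `n x 2` matrix of (x, y) centers (optional).
#' @param out_path Output PNG path.
#' @param color RGB triplet, default blue.
#' @return `out_path`, invisibly.
#' @export
render_overlay <- function(image, detections = NULL, centers = NULL,
                           out_path, color = c(0L, 0L, 255L)) {
  px <- if (inherits(image, "annotated_image")) image$pixels else image
  px <- px + 0L   # copy
  H <- dim(px)[1]; W <- dim(px)[2]
  paint <- function(rows, cols) {
    rows <- rows[rows >= 1 & rows <= H]
    cols <- cols[cols >= 1 & cols <= W]
    if (length(rows) == 0L || length(cols) == 0L) return()
    for (c in 1:3) px[rows, cols, c] <<- color[c]
  }
  if (!is.null(detections) && nrow(detections) > 0) {
    for (i in seq_len(nrow(detections))) {
      x0 <- round(detections$x[i]) + 1L; y0 <- round(detections$y[i]) + 1L
      x1 <- x0 + round(detections$width[i]) - 1L
      y1 <- y0 + round(detections$height[i]) - 1L
      paint(y0:y1, c(x0, x1))
      paint(c(y0, y1), x0:x1)
    }
  }
  if (!is.null(centers) && nrow(centers) > 0) {
    for (i in seq_len(nrow(centers))) {
      cx <- floor(centers[i, 1]) + 1L; cy <- floor(centers[i, 2]) + 1L
      for (dy in -2:2) for (dx in -2:2) {
        if (dx^2 + dy^2 <= 4 && cy + dy >= 1 && cy + dy <= H &&
            cx + dx >= 1 && cx + dx <= W) {
          px[cy + dy, cx + dx, ] <- color
        }
      }
    }
  }
  write_image(clamp_u8(px), out_path)
  invisible(out_path)
}

#' Write detections as CSV
#' @param detections Data frame (`x`, `y`, `width`, `height`, `confidence`).
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_detections <- function(detections, path) {
  write.csv(detections, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save a trained model with a JSON sidecar
#'
#' The model is serialized with [saveRDS()]; a `<path>.json` sidecar records
#' the class, configuration, seed and package version so a run can be
#' reproduced from the sidecar alone.
#'
#' @param model A `kernel_classifier`, `center_regressor` or `hog_svm`.
#' @param path Output path (conventionally `.rds`).
#' @return The path, invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  write_sidecar(path, list(class = class(model)[1],
                           config = model$config,
                           rng_seed = model$rng_seed))
  invisible(path)
}

#' Load a model saved by [save_model()]
#' @param path Path to the `.rds` checkpoint.
#' @return The model object.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("no such model file: ", path, call. = FALSE)
  m <- readRDS(path)
  if (!inherits(m, c("kernel_classifier", "center_regressor", "hog_svm"))) {
    stop("file does not contain a maizecount model", call. = FALSE)
  }
  m
}

# JSON sidecar next to an artifact: configuration + seed + version.
write_sidecar <- function(path, info) {
  info$package <- "maizecount"
  info$version <- as.character(utils::packageVersion("maizecount"))
  info$written <- iso_timestamp()
  jsonlite::write_json(info, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(path)
}

#' Persist a patch dataset as PNG patches plus a CSV manifest
#'
#' @param dataset A [patch_dataset()].
#' @param dir Output directory (created if needed); patches are written as
#'   `patch_00001.png, ...` with a `manifest.csv`
#'   (`file,label,center_x,center_y`).
#' @return `dir`, invisibly.
#' @export
write_patch_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "patch_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(dataset)
  files <- sprintf("patch_%05d.png", seq_len(n))
  cx <- rep(NA_real_, n); cy <- rep(NA_real_, n)
  labs <- character(n)
  for (i in seq_len(n)) {
    p <- dataset$patches[[i]]
    write_image(p$pixels, file.path(dir, files[i]))
    labs[i] <- p$label
    if (!is.null(p$center)) { cx[i] <- p$center[1]; cy[i] <- p$center[2] }
  }
  manifest <- data.frame(file = files, label = labs,
                         center_x = cx, center_y = cy)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE,
            quote = FALSE)
  write_sidecar(file.path(dir, "manifest.csv"),
                list(n = n, rng_seed = dataset$rng_seed))
  invisible(dir)
}

#' Load a patch dataset written by [write_patch_dataset()]
#' @param dir Dataset directory.
#' @return A [patch_dataset()].
#' @export
read_patch_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop("no manifest.csv under ", dir, call. = FALSE)
  manifest <- read.csv(mf, stringsAsFactors = FALSE)
  patches <- lapply(seq_len(nrow(manifest)), function(i) {
    px <- read_image(file.path(dir, manifest$file[i]))
    ctr <- if (!is.na(manifest$center_x[i])) {
      c(manifest$center_x[i], manifest$center_y[i])
    }
    patch(px, manifest$label[i], center = ctr)
  })
  patch_dataset(patches)
}
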