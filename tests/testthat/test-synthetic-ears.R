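# The synthetic scene generator: exact lattice counts, determinism, spacing
# guarantees, annotation consistency, and multi-ear placement.

test_that("a degenerate lattice renders exactly columns x rows kernels", {
  p <- ear_scene_params(image_size = c(2000, 900), visible_columns = c(14, 14),
                        kernels_per_column = c(30, 30), jitter = 0,
                        rng_seed = 1)
  img <- render_ear_image(p)
  expect_equal(nrow(img$centers), 14 * 30)
  # whole-ear ground truth: visible columns are 40% of the ear
  expect_equal(img$total_kernels, round(2.5 * 14) * 30)
})

test_that("rendering is bit-identical under a fixed seed", {
  p <- small_scene_params(42)
  a <- render_ear_image(p)
  b <- render_ear_image(p)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$centers, b$centers)
  expect_identical(a$boxes, b$boxes)
})

test_that("pairwise center distances never fall below the kernel radius", {
  for (s in 1:5) {
    p <- ear_scene_params(image_size = c(1024, 400), kernel_radius = c(6, 6),
                          rng_seed = s)
    img <- render_ear_image(p)
    d <- stats::dist(img$centers)
    expect_gte(min(d), 6)
  }
})

test_that("annotations are consistent: centers in bounds, in boxes, on kernels", {
  img <- small_scene(7)
  H <- dim(img$pixels)[1]; W <- dim(img$pixels)[2]
  expect_true(all(img$centers[, "x"] >= 0 & img$centers[, "x"] < W))
  expect_true(all(img$centers[, "y"] >= 0 & img$centers[, "y"] < H))
  expect_equal(nrow(img$boxes), nrow(img$centers))
  expect_true(all(img$centers[, "x"] >= img$boxes[, "x"] &
                  img$centers[, "x"] < img$boxes[, "x"] + img$boxes[, "width"]))
  # every center sits on a rendered (bright) kernel pixel, i.e. inside the
  # ear silhouette
  r_at_centers <- img$pixels[cbind(floor(img$centers[, "y"]) + 1,
                                   floor(img$centers[, "x"]) + 1, 1)]
  expect_true(all(r_at_centers > 100))
})

test_that("parameter validation rejects impossible scenes", {
  expect_error(ear_scene_params(image_size = c(32, 32)), "64")
  expect_error(ear_scene_params(kernel_radius = c(2, 2)), "kernel_radius")
  expect_error(ear_scene_params(visible_columns = c(5, 3)), "visible_columns")
  # image too small for the requested ear
  p <- ear_scene_params(image_size = c(100, 100), rng_seed = 1)
  expect_error(render_ear_image(p), "too small")
})

batch_params <- function(seed, n_ears = 3L) {
  ear_scene_params(image_size = c(640, 640), n_ears = n_ears,
                   kernels_per_column = c(6, 8), visible_columns = c(4, 5),
                   kernel_radius = c(5, 6), rng_seed = seed)
}

test_that("batch scenes pool centers additively and keep per-ear identity", {
  p <- ear_scene_params(image_size = c(760, 760), n_ears = 3L,
                        kernels_per_column = c(8, 8), visible_columns = c(5, 5),
                        kernel_radius = c(6, 6), rng_seed = 3)
  img <- render_batch_scene(p)
  expect_equal(nrow(img$centers), 3 * 5 * 8)
  expect_setequal(unique(img$ear), 1:3)
  expect_identical(render_batch_scene(p)$centers, img$centers)
  expect_error(render_batch_scene(ear_scene_params(n_ears = 1L)), "n_ears")
})

test_that("ears in batch scenes occupy disjoint regions over many seeds", {
  for (s in 1:100) {
    img <- render_batch_scene(batch_params(s))
    # bounding boxes of per-ear centers must be pairwise disjoint
    bbs <- lapply(split(seq_len(nrow(img$centers)), img$ear), function(i) {
      c(range(img$centers[i, "x"]), range(img$centers[i, "y"]))
    })
    for (i in seq_along(bbs)) {
      for (j in seq_len(i - 1L)) {
        a <- bbs[[i]]; b <- bbs[[j]]
        overlap_x <- a[1] <= b[2] && b[1] <= a[2]
        overlap_y <- a[3] <= b[4] && b[3] <= a[4]
        expect_false(overlap_x && overlap_y)
      }
    }
  }
})

test_that("nuisance factors are covered: backgrounds and tilts span the ranges", {
  bgs <- character(100); tilts <- numeric(100)
  for (s in 1:100) {
    img <- render_ear_image(small_scene_params(s, background_class = "random",
                                               ear_tilt = c(-10, 10)))
    bgs[s] <- img$background
    tilts[s] <- img$tilt
  }
  expect_setequal(unique(bgs), c("soil", "grass", "hand", "plain"))
  expect_lt(min(tilts), -7)
  expect_gt(max(tilts), 7)
  expect_true(all(tilts >= -10 & tilts <= 10))
})
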