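test_that("YOLO label files parse and round-trip", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  writeLines("0 0.5 0.5 0.2 0.1", tmp)
  b <- readYoloLabels(tmp)
  expect_equal(nrow(b), 1L)
  expect_equal(unlist(b[1, ]), c(class_id = 0, cx = 0.5, cy = 0.5,
                                 w = 0.2, h = 0.1))
  writeLines(character(), tmp)
  expect_equal(nrow(readYoloLabels(tmp)), 0L)

  boxes <- ATWquant:::.with_seed(77, yoloBoxes(
    sample(0:3, 100, replace = TRUE),
    stats::runif(100, 0.2, 0.8), stats::runif(100, 0.2, 0.8),
    stats::runif(100, 0.01, 0.3), stats::runif(100, 0.01, 0.3)))
  writeYoloLabels(boxes, tmp)
  back <- readYoloLabels(tmp)
  expect_equal(back$class_id, boxes$class_id)
  for (col in c("cx", "cy", "w", "h"))
    expect_true(all(abs(back[[col]] - boxes[[col]]) < 1e-6))
})

test_that("malformed label lines fail with their line number", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 0.5 0.5 0.2 0.1", "0 0.5 0.5 0.2"), tmp)
  expect_error(readYoloLabels(tmp), ":2:")
  writeLines(c("0 0.5 0.5 0.2 0.1", "0 1.5 0.5 0.2 0.1"), tmp)
  expect_error(readYoloLabels(tmp), "normalized")
  writeLines("0 a b c d", tmp)
  expect_error(readYoloLabels(tmp), "non-numeric")
})

test_that("the split rule reproduces the canonical 8:1:1 sizes", {
  m <- splitDataset(seq_len(3358), seed = 42)
  expect_equal(as.integer(table(m$split)), c(2687L, 336L, 335L))
  expect_setequal(m$id, seq_len(3358))
  m10 <- splitDataset(seq_len(10), seed = 1)
  expect_equal(as.integer(table(m10$split)), c(8L, 1L, 1L))
  expect_identical(splitDataset(1:100, seed = 9),
                   splitDataset(1:100, seed = 9))
  expect_false(identical(splitDataset(1:100, seed = 9)$split,
                         splitDataset(1:100, seed = 10)$split))
  expect_error(splitDataset(1:2), "at least 3")
})

test_that("identity and pure-translation affine transforms act exactly", {
  img <- random_image(16, 16, 3)
  boxes <- yoloBoxes(0L, 0.5, 0.5, 0.25, 0.25)
  res <- affineTransform(img, boxes)
  expect_equal(res$image, img)
  expect_equal(res$boxes, boxes)
  res <- affineTransform(img, boxes, translate = c(0.25, 0.125))
  expect_equal(res$boxes$cx, 0.75)
  expect_equal(res$boxes$cy, 0.625)
  expect_equal(res$boxes$w, 0.25)
  # raster shifted by 4 columns / 2 rows, exposed band filled with 0
  expect_equal(res$image[3:16, 5:16, ], img[1:14, 1:12, ])
  expect_true(all(res$image[, 1:4, ] == 0))
})

test_that("rotating a centered box by 90 degrees swaps its extents", {
  boxes <- yoloBoxes(0L, 0.5, 0.5, 0.4, 0.2)
  res <- affineTransform(random_image(12, 12, 4), boxes, angle = 90)
  expect_equal(res$boxes$w, 0.2, tolerance = 1e-12)
  expect_equal(res$boxes$h, 0.4, tolerance = 1e-12)
  # corner-transform oracle for a generic angle: bbox of rotated corners
  ang <- 30; th <- ang * pi / 180
  res <- affineTransform(random_image(12, 12, 4), boxes, angle = ang)
  corn <- rbind(c(-0.2, -0.1), c(0.2, -0.1), c(-0.2, 0.1), c(0.2, 0.1))
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- corn %*% t(R)
  expect_equal(res$boxes$w, diff(range(rot[, 1])), tolerance = 1e-12)
  expect_equal(res$boxes$h, diff(range(rot[, 2])), tolerance = 1e-12)
})

test_that("boxes are clipped and dropped by the affine remap", {
  boxes <- yoloBoxes(c(0L, 0L), c(0.1, 0.9), c(0.5, 0.5), c(0.15, 0.1),
                     c(0.15, 0.1))
  res <- affineTransform(random_image(16, 16, 5), boxes,
                         translate = c(-0.12, 0))
  # first box clipped at the left edge, second survives intact
  expect_equal(nrow(res$boxes), 2L)
  expect_lt(res$boxes$w[1], 0.15)
  res <- affineTransform(random_image(16, 16, 5), boxes,
                         translate = c(-0.5, 0))
  expect_equal(nrow(res$boxes), 1L)   # first box fully off-frame
})

test_that("color distortion honors its photometric contracts", {
  img <- uniform_image(c(128, 128, 128), 8, 8)
  expect_equal(colorDistort(img), img)
  shifted <- colorDistort(img, brightness = 0.2)
  expect_equal(mean(shifted) - mean(img), 0.2, tolerance = 1e-3)
  gray <- colorDistort(random_image(8, 8, 21), saturation = 0)
  expect_equal(gray[, , 1], gray[, , 2])
  expect_equal(gray[, , 2], gray[, , 3])
  # HSV oracle: grDevices round trip reproduces our hsv->rgb inverse
  x <- random_image(6, 6, 22)
  back <- colorDistort(x, saturation = 1, hue = 1e-12)
  expect_equal(back, x, tolerance = 1e-6)
  lessSat <- colorDistort(x, saturation = 0.5)
  satOf <- function(im) {
    m <- rbind(as.vector(im[, , 1]), as.vector(im[, , 2]),
               as.vector(im[, , 3]))
    grDevices::rgb2hsv(m, maxColorValue = 1)[2, ]
  }
  expect_equal(satOf(lessSat), satOf(x) * 0.5, tolerance = 1e-6)
})

test_that("Gaussian noise is seeded, centered and clamp-bounded", {
  img <- uniform_image(c(120, 120, 120), 32, 32)
  expect_identical(gaussianNoise(img, 0), img)
  n1 <- gaussianNoise(img, 0.05, seed = 9)
  n2 <- gaussianNoise(img, 0.05, seed = 9)
  expect_identical(n1, n2)
  expect_false(identical(n1, gaussianNoise(img, 0.05, seed = 10)))
  resid <- n1 - img
  # sample mean within 3 sigma / sqrt(n) of zero (no clipping at 0.47)
  expect_lt(abs(mean(resid)), 3 * 0.05 / sqrt(length(resid)))
  expect_true(all(n1 >= 0 & n1 <= 1))
})

test_that("cutout masks the stated area and leaves labels untouched", {
  img <- random_image(32, 32, 31)
  boxes <- yoloBoxes(0L, 0.5, 0.5, 0.5, 0.5)
  res <- cutout(img, boxes, nPatches = 0)
  expect_identical(res$image, img)
  res <- cutout(img, boxes, nPatches = 1, patchSize = c(0.25, 0.25),
                seed = 5)
  expect_equal(res$boxes, boxes)
  changed <- which(res$image[, , 1] != img[, , 1], arr.ind = TRUE)
  expect_lte(nrow(changed), 8 * 8)       # one quarter-side patch
  expect_gt(nrow(changed), 0)
  fullPatch <- cutout(img, boxes, nPatches = 1, patchSize = c(2, 2))
  for (ch in 1:3)
    expect_equal(unique(as.vector(fullPatch$image[, , ch])),
                 mean(img[, , ch]))
  occl <- cutout(img, boxes, nPatches = 1, patchSize = c(2, 2),
                 dropOccluded = TRUE)
  expect_equal(nrow(occl$boxes), 0L)
  expect_identical(cutout(img, boxes, 3, seed = 8)$image,
                   cutout(img, boxes, 3, seed = 8)$image)
})

test_that("mosaic composes quadrants and remaps boxes at half scale", {
  img <- random_image(20, 20, 41)
  boxes <- yoloBoxes(0L, 0.5, 0.5, 0.3, 0.2)
  four <- replicate(4, list(image = img, boxes = boxes), simplify = FALSE)
  res <- mosaic(four, canvasSize = c(64, 64), jitter = 0)
  expect_equal(res$center, c(0.5, 0.5))
  expect_equal(nrow(res$boxes), 4L)
  expect_equal(res$boxes$w, rep(0.15, 4))
  expect_equal(res$boxes$h, rep(0.1, 4))
  expect_setequal(round(res$boxes$cx, 6), c(0.25, 0.75))
  expect_setequal(round(res$boxes$cy, 6), c(0.25, 0.75))
  # all quadrants carry the same resampled content
  expect_equal(res$image[1:32, 1:32, ], res$image[1:32, 33:64, ])
  expect_equal(res$image[1:32, 1:32, ], res$image[33:64, 33:64, ])
  expect_identical(mosaic(four, jitter = 0.2, seed = 3),
                   mosaic(four, jitter = 0.2, seed = 3))
  jit <- mosaic(four, canvasSize = c(64, 64), jitter = 0.2, seed = 3)
  co <- cbind(jit$boxes$cx - jit$boxes$w / 2, jit$boxes$cy - jit$boxes$h / 2,
              jit$boxes$cx + jit$boxes$w / 2, jit$boxes$cy + jit$boxes$h / 2)
  expect_true(all(co >= -1e-12 & co <= 1 + 1e-12))
})

test_that("environment presets move the statistics they claim to move", {
  img <- random_image(24, 24, 51)
  lum <- function(im) 0.2126 * im[, , 1] + 0.7152 * im[, , 2] +
    0.0722 * im[, , 3]
  expect_lt(mean(lum(environmentPreset(img, "dim"))), mean(lum(img)))
  expect_gt(mean(lum(environmentPreset(img, "direct_sun"))),
            mean(lum(img)))
  expect_lt(stats::sd(lum(environmentPreset(img, "fog"))),
            stats::sd(lum(img)))
  n1 <- environmentPreset(img, "noise", seed = 2)
  expect_identical(n1, environmentPreset(img, "noise", seed = 2))
  expect_false(identical(n1, img))
})

test_that("augmentations preserve box validity on random pipelines", {
  for (seed in 1:6) {
    img <- random_image(24, 24, seed)
    boxes <- ATWquant:::.with_seed(seed + 300, yoloBoxes(
      rep(0L, 5), stats::runif(5, 0.2, 0.8), stats::runif(5, 0.2, 0.8),
      stats::runif(5, 0.05, 0.3), stats::runif(5, 0.05, 0.3)))
    res <- affineTransform(img, boxes,
                           angle = seed * 17, translate = c(0.07, -0.05),
                           scale = 0.9 + 0.05 * seed)
    res <- cutout(res$image, res$boxes, nPatches = 2, seed = seed)
    b <- res$boxes
    if (nrow(b)) {
      expect_true(all(b$cx >= 0 & b$cx <= 1 & b$cy >= 0 & b$cy <= 1))
      expect_true(all(b$w > 0 & b$h > 0))
      expect_true(all(b$cx - b$w / 2 >= -1e-9 & b$cx + b$w / 2 <= 1 + 1e-9))
    }
  }
})
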