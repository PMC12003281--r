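# Dataset construction: YOLO-format label I/O, the 8:1:1 split, and the
# box-aware augmentation operators (affine, color distortion, Gaussian noise,
# Cutout, Mosaic) plus environmental presets.

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else suppressWarnings(rm(".Random.seed", envir = globalenv()))
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Read and write YOLO-format label files
#'
#' One object per line, whitespace separated:
#' \code{class cx cy w h}, all coordinates normalized to [0, 1] and
#' center-based. An empty file denotes an image with no targets. Writing
#' uses 6 decimal places, so a write/read round trip is an identity to 1e-6.
#'
#' @param path label file path (.txt).
#' @return \code{readYoloLabels}: a box data.frame (see [yoloBoxes()]).
#' @export
readYoloLabels <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (!length(keep))
    return(yoloBoxes(integer(), numeric(), numeric(), numeric(), numeric()))
  rows <- lapply(keep, function(i) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 5L)
      stop(sprintf("%s:%d: expected 5 fields 'class cx cy w h', got %d",
                   path, i, length(parts)))
    vals <- suppressWarnings(as.numeric(parts))
    if (any(is.na(vals)))
      stop(sprintf("%s:%d: non-numeric field in '%s'", path, i, lines[i]))
    if (any(vals[2:5] < 0 | vals[2:5] > 1))
      stop(sprintf("%s:%d: coordinates must be normalized to [0, 1]",
                   path, i))
    vals
  })
  m <- do.call(rbind, rows)
  yoloBoxes(m[, 1], m[, 2], m[, 3], m[, 4], m[, 5])
}

#' @rdname readYoloLabels
#' @param boxes a box data.frame.
#' @export
writeYoloLabels <- function(boxes, path) {
  .check_boxes(boxes)
  lines <- sprintf("%d %.6f %.6f %.6f %.6f", boxes$class_id,
                   boxes$cx, boxes$cy, boxes$w, boxes$h)
  writeLines(lines, path)
  invisible(path)
}

#' Split a dataset into train/validation/test sets
#'
#' Seeded uniform shuffle followed by a deterministic size rule:
#' \code{nVal = round(r2 * N)} (half-up), \code{nTest = floor(r3 * N)}, and
#' the remainder trains. At the canonical 8:1:1 ratio and N = 3358 this
#' yields 2687 / 336 / 335 (plain rounding of all three parts does not).
#'
#' @param ids vector of item identifiers (length N >= 3).
#' @param ratios train/val/test proportions summing to 1.
#' @param seed integer seed for the shuffle.
#' @return data.frame with columns \code{id} and
#'   \code{split} (factor: train/val/test).
#' @export
splitDataset <- function(ids, ratios = c(0.8, 0.1, 0.1), seed = 1) {
  n <- length(ids)
  if (n < 3L) stop("need at least 3 items to form three splits")
  if (length(ratios) != 3L || abs(sum(ratios) - 1) > 1e-9 || any(ratios < 0))
    stop("ratios must be 3 non-negative values summing to 1")
  nVal <- as.integer(.round_half_up(ratios[2] * n, 0))
  nTest <- as.integer(floor(ratios[3] * n))
  nTrain <- n - nVal - nTest
  if (min(nTrain, nVal, nTest) < 1L)
    stop("each split must receive at least one item")
  perm <- .with_seed(seed, sample.int(n))
  split <- factor(rep(c("train", "val", "test"), c(nTrain, nVal, nTest)),
                  levels = c("train", "val", "test"))
  out <- data.frame(id = ids[perm], split = split)
  out[order(perm), , drop = FALSE]
}

# ---- raster helpers ---------------------------------------------------------

.clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Inverse-map nearest-neighbour sampling: for each output pixel center
# (normalized coords, origin top-left, y down), `invMap(x, y)` returns source
# coordinates; out-of-frame samples take `fill`.
.warp_nn <- function(img, invMap, outDim = dim(img)[1:2], fill = 0) {
  H <- outDim[1]; W <- outDim[2]
  hs <- dim(img)[1]; ws <- dim(img)[2]
  gx <- rep((seq_len(W) - 0.5) / W, each = H)
  gy <- rep((seq_len(H) - 0.5) / H, times = W)
  src <- invMap(gx, gy)
  sx <- floor(src$x * ws) + 1
  sy <- floor(src$y * hs) + 1
  inside <- sx >= 1 & sx <= ws & sy >= 1 & sy <= hs
  sx[!inside] <- 1L; sy[!inside] <- 1L
  out <- array(fill, c(H, W, 3))
  for (ch in 1:3) {
    v <- img[, , ch][cbind(sy, sx)]
    v[!inside] <- fill
    out[, , ch] <- matrix(v, H, W)
  }
  out
}

# Clip boxes to the unit square; drop empty/degenerate remains.
.clip_boxes <- function(boxes, minArea = 0) {
  if (!nrow(boxes)) return(boxes)
  co <- .corners(boxes)
  x1 <- pmax(co[, 1], 0); y1 <- pmax(co[, 2], 0)
  x2 <- pmin(co[, 3], 1); y2 <- pmin(co[, 4], 1)
  w <- x2 - x1; h <- y2 - y1
  keep <- w > 0 & h > 0 & (w * h) >= minArea
  data.frame(class_id = boxes$class_id[keep],
             cx = ((x1 + x2) / 2)[keep], cy = ((y1 + y2) / 2)[keep],
             w = w[keep], h = h[keep])
}

#' Affine augmentation of an image and its boxes
#'
#' Rotation (degrees, about the image center), isotropic scaling (about the
#' center) and translation, applied in normalized coordinates (origin
#' top-left, y down). The raster is resampled by inverse-map
#' nearest-neighbour lookup; exposed regions take \code{fill}. Each box is
#' re-derived as the axis-aligned bounding box of its four transformed
#' corners, clipped to the frame, and dropped when its clipped area falls
#' below \code{minArea}.
#'
#' @param img H x W x 3 array in [0, 1].
#' @param boxes box data.frame (may be empty).
#' @param angle rotation in degrees (positive = clockwise on screen).
#' @param translate normalized \code{c(tx, ty)} shift.
#' @param scale isotropic scale factor (> 0).
#' @param minArea minimum normalized box area kept after clipping.
#' @param fill fill value for exposed raster regions.
#' @return list with \code{image} and \code{boxes}.
#' @export
affineTransform <- function(img, boxes = NULL, angle = 0,
                            translate = c(0, 0), scale = 1,
                            minArea = 1e-4, fill = 0) {
  img <- .as_rgb_array(img)
  if (is.null(boxes))
    boxes <- yoloBoxes(integer(), numeric(), numeric(), numeric(), numeric())
  .check_boxes(boxes)
  if (scale <= 0) stop("scale must be positive")
  th <- angle * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)  # y-down convention
  fwd <- function(x, y) {
    p <- R %*% rbind(x - 0.5, y - 0.5) * scale
    list(x = p[1, ] + 0.5 + translate[1], y = p[2, ] + 0.5 + translate[2])
  }
  inv <- function(x, y) {
    p <- t(R) %*% rbind(x - 0.5 - translate[1], y - 0.5 - translate[2]) / scale
    list(x = p[1, ] + 0.5, y = p[2, ] + 0.5)
  }
  outImg <- .warp_nn(img, inv, fill = fill)
  if (nrow(boxes)) {
    co <- .corners(boxes)
    xs <- cbind(co[, 1], co[, 3], co[, 1], co[, 3])
    ys <- cbind(co[, 2], co[, 2], co[, 4], co[, 4])
    tc <- fwd(as.vector(xs), as.vector(ys))
    tx <- matrix(tc$x, nrow(boxes)); ty <- matrix(tc$y, nrow(boxes))
    x1 <- apply(tx, 1, min); x2 <- apply(tx, 1, max)
    y1 <- apply(ty, 1, min); y2 <- apply(ty, 1, max)
    boxes <- .clip_boxes(data.frame(class_id = boxes$class_id,
                                    cx = (x1 + x2) / 2, cy = (y1 + y2) / 2,
                                    w = x2 - x1, h = y2 - y1), minArea)
  }
  list(image = outImg, boxes = boxes)
}

# Vectorized HSV -> RGB (h, s, v in [0, 1]); inverse of grDevices::rgb2hsv.
.hsv_to_rgb <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6) %% 6
  f <- h6 - floor(h6)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  cbind(r, g, b)
}

#' Photometric color distortion
#'
#' Brightness and contrast act in RGB
#' (\code{out = (in - 0.5) * contrast + 0.5 + brightness}, clamped);
#' saturation and hue act in HSV (saturation multiplied, hue shifted
#' cyclically). Labels are unaffected by photometric changes.
#'
#' @param img H x W x 3 array in [0, 1].
#' @param brightness additive offset in [-1, 1].
#' @param contrast multiplicative contrast factor (>= 0; 1 = identity).
#' @param saturation saturation factor (>= 0; 0 grays the image out).
#' @param hue cyclic hue shift in [0, 1) turns.
#' @return distorted H x W x 3 array in [0, 1].
#' @export
colorDistort <- function(img, brightness = 0, contrast = 1,
                         saturation = 1, hue = 0) {
  img <- .as_rgb_array(img)
  if (contrast < 0 || saturation < 0)
    stop("contrast and saturation factors must be non-negative")
  out <- .clamp01((img - 0.5) * contrast + 0.5 + brightness)
  if (saturation != 1 || hue != 0) {
    d <- dim(out)
    rgb <- rbind(as.vector(out[, , 1]), as.vector(out[, , 2]),
                 as.vector(out[, , 3]))
    hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
    res <- .hsv_to_rgb((hsv[1, ] + hue) %% 1,
                       .clamp01(hsv[2, ] * saturation),
                       hsv[3, ])
    out <- array(c(res[, 1], res[, 2], res[, 3]), d)
  }
  out
}

#' Additive Gaussian pixel noise
#'
#' Adds i.i.d. N(0, sigma^2) noise to every channel and clamps to [0, 1];
#' emulates sensor/transmission noise. Bit-reproducible under a fixed seed.
#'
#' @param img H x W x 3 array in [0, 1].
#' @param sigma noise standard deviation in [0, 1] intensity units.
#' @param seed integer seed (NULL uses the current RNG stream).
#' @return noisy image array.
#' @export
gaussianNoise <- function(img, sigma, seed = NULL) {
  img <- .as_rgb_array(img)
  if (sigma < 0) stop("sigma must be non-negative")
  if (sigma == 0) return(img)
  noise <- .with_seed(seed, stats::rnorm(length(img), 0, sigma))
  .clamp01(img + array(noise, dim(img)))
}

#' Cutout augmentation
#'
#' Masks \code{nPatches} axis-aligned rectangles (normalized size
#' \code{patchSize}) at seeded uniform positions, filling them with the
#' image's per-channel mean color. Labels are left untouched by default
#' (occlusion-regularization semantics); with \code{dropOccluded = TRUE},
#' boxes whose area is at least \code{occlusionThr} covered by patches are
#' removed.
#'
#' @param img H x W x 3 array in [0, 1].
#' @param boxes box data.frame.
#' @param nPatches number of rectangles (0 = identity).
#' @param patchSize normalized \code{c(w, h)} of each rectangle.
#' @param seed integer seed.
#' @param dropOccluded drop heavily occluded boxes?
#' @param occlusionThr covered-area fraction above which a box is dropped.
#' @return list with \code{image} and \code{boxes}.
#' @export
cutout <- function(img, boxes = NULL, nPatches, patchSize = c(0.1, 0.1),
                   seed = NULL, dropOccluded = FALSE, occlusionThr = 0.8) {
  img <- .as_rgb_array(img)
  if (is.null(boxes))
    boxes <- yoloBoxes(integer(), numeric(), numeric(), numeric(), numeric())
  .check_boxes(boxes)
  if (nPatches == 0) return(list(image = img, boxes = boxes))
  H <- dim(img)[1]; W <- dim(img)[2]
  centers <- .with_seed(seed, matrix(stats::runif(2 * nPatches), ncol = 2))
  fillCol <- vapply(1:3, function(ch) mean(img[, , ch]), numeric(1))
  covered <- matrix(FALSE, H, W)
  for (k in seq_len(nPatches)) {
    x1 <- max(1L, floor((centers[k, 1] - patchSize[1] / 2) * W) + 1L)
    x2 <- min(W, floor((centers[k, 1] + patchSize[1] / 2) * W))
    y1 <- max(1L, floor((centers[k, 2] - patchSize[2] / 2) * H) + 1L)
    y2 <- min(H, floor((centers[k, 2] + patchSize[2] / 2) * H))
    if (x1 > x2 || y1 > y2) next
    for (ch in 1:3) img[y1:y2, x1:x2, ch] <- fillCol[ch]
    covered[y1:y2, x1:x2] <- TRUE
  }
  if (dropOccluded && nrow(boxes)) {
    frac <- vapply(seq_len(nrow(boxes)), function(i) {
      co <- .corners(boxes[i, , drop = FALSE])
      xs <- max(1L, ceiling(co[1] * W)):min(W, floor(co[3] * W))
      ys <- max(1L, ceiling(co[2] * H)):min(H, floor(co[4] * H))
      mean(covered[ys, xs, drop = FALSE])
    }, numeric(1))
    boxes <- boxes[frac < occlusionThr, , drop = FALSE]
  }
  list(image = img, boxes = boxes)
}

#' Mosaic augmentation
#'
#' Composes four labeled images into one canvas, 2 x 2 about a jittered
#' center point. Each source image is resized (nearest-neighbour) into its
#' quadrant; its boxes are remapped into the quadrant's normalized extent
#' and clipped to the canvas. A clipped box is dropped when its width or
#' height falls below 2 canvas pixels or its area falls below 1% of its
#' pre-clip mapped area.
#'
#' @param four list of 4 lists, each \code{list(image =, boxes =)}; order is
#'   top-left, top-right, bottom-left, bottom-right.
#' @param canvasSize output \code{c(H, W)} in pixels.
#' @param jitter maximum absolute jitter of the center point (normalized;
#'   0 puts the center at (0.5, 0.5) exactly).
#' @param seed integer seed for the jitter.
#' @return list with \code{image} (H x W x 3) and \code{boxes}.
#' @export
mosaic <- function(four, canvasSize = c(256, 256), jitter = 0.1,
                   seed = NULL) {
  if (length(four) != 4L) stop("mosaic needs exactly 4 labeled images")
  for (f in four) .check_boxes(f$boxes)
  H <- canvasSize[1]; W <- canvasSize[2]
  ctr <- 0.5 + .with_seed(seed, stats::runif(2, -jitter, jitter))
  cx <- min(max(ctr[1], 0.1), 0.9); cy <- min(max(ctr[2], 0.1), 0.9)
  # quadrant extents in normalized canvas coords: (x0, x1, y0, y1)
  quads <- list(c(0, cx, 0, cy), c(cx, 1, 0, cy),
                c(0, cx, cy, 1), c(cx, 1, cy, 1))
  canvas <- array(0, c(H, W, 3))
  outBoxes <- list()
  for (q in 1:4) {
    ext <- quads[[q]]
    xs <- (floor(ext[1] * W) + 1L):floor(ext[2] * W)
    ys <- (floor(ext[3] * H) + 1L):floor(ext[4] * H)
    sub <- .warp_nn(.as_rgb_array(four[[q]]$image), function(x, y)
      list(x = x, y = y), outDim = c(length(ys), length(xs)))
    canvas[ys, xs, ] <- sub
    b <- four[[q]]$boxes
    if (!nrow(b)) next
    sw <- ext[2] - ext[1]; sh <- ext[4] - ext[3]
    mapped <- data.frame(class_id = b$class_id,
                         cx = ext[1] + b$cx * sw, cy = ext[3] + b$cy * sh,
                         w = b$w * sw, h = b$h * sh)
    preArea <- mapped$w * mapped$h
    clipped <- .clip_boxes_keep(mapped)
    keep <- clipped$w >= 2 / W & clipped$h >= 2 / H &
            clipped$w * clipped$h >= 0.01 * preArea[clipped$src]
    outBoxes[[q]] <- clipped[keep, setdiff(names(clipped), "src"),
                             drop = FALSE]
  }
  outBoxes <- Filter(Negate(is.null), outBoxes)
  boxes <- if (length(outBoxes)) do.call(rbind, outBoxes)
           else yoloBoxes(integer(), numeric(), numeric(), numeric(),
                          numeric())
  rownames(boxes) <- NULL
  list(image = canvas, boxes = boxes, center = c(cx, cy))
}

# Like .clip_boxes but keeps the source-row index for area bookkeeping.
.clip_boxes_keep <- function(boxes) {
  co <- .corners(boxes)
  x1 <- pmax(co[, 1], 0); y1 <- pmax(co[, 2], 0)
  x2 <- pmin(co[, 3], 1); y2 <- pmin(co[, 4], 1)
  w <- x2 - x1; h <- y2 - y1
  keep <- which(w > 0 & h > 0)
  data.frame(class_id = boxes$class_id[keep],
             cx = ((x1 + x2) / 2)[keep], cy = ((y1 + y2) / 2)[keep],
             w = w[keep], h = h[keep], src = keep)
}

#' Environmental-condition presets
#'
#' Parameter bundles over the photometric/noise operators that emulate field
#' conditions: \code{direct_sun} (brightness and saturation up), \code{dim}
#' (brightness and saturation down), \code{fog} (contrast reduction plus an
#' additive white haze, lowering RMS contrast), and \code{noise} (Gaussian
#' sensor noise).
#'
#' @param img H x W x 3 array in [0, 1].
#' @param preset one of \code{"direct_sun"}, \code{"dim"}, \code{"fog"},
#'   \code{"noise"}.
#' @param seed integer seed (used by the \code{noise} preset).
#' @return transformed image array.
#' @export
environmentPreset <- function(img,
                              preset = c("direct_sun", "dim", "fog",
                                         "noise"),
                              seed = NULL) {
  preset <- match.arg(preset)
  img <- .as_rgb_array(img)
  switch(preset,
    direct_sun = colorDistort(img, brightness = 0.15, saturation = 1.25),
    dim = colorDistort(img, brightness = -0.25, saturation = 0.8),
    fog = {
      low <- colorDistort(img, contrast = 0.5)
      .clamp01(low * 0.7 + 0.3)          # additive haze toward white
    },
    noise = gaussianNoise(img, sigma = 0.05, seed = seed)
  )
}
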