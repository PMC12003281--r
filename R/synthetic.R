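# Synthetic fixture generators: activation fields rendered through a
# jet-style colormap (heat-map fixtures with analytically known colors) and
# detection scenarios with prescribed TP/FP/FN outcomes. Everything is
# seeded and bit-reproducible, so the whole toolkit is testable without any
# real trained detector or field imagery.

#' Synthetic class-activation field
#'
#' A sum of isotropic Gaussian blobs on the unit square, evaluated at pixel
#' centers and clamped to [0, 1] — a stand-in for the activation intensity a
#' class-activation method would produce.
#'
#' @param shape \code{c(H, W)} in pixels.
#' @param blobs list of \code{list(center = c(x, y), sigma =, amplitude =)}
#'   in normalized coordinates; an empty list gives the all-zero field.
#' @return H x W numeric matrix in [0, 1].
#' @export
makeActivationField <- function(shape, blobs = list()) {
  H <- shape[1]; W <- shape[2]
  gx <- matrix(rep((seq_len(W) - 0.5) / W, each = H), H, W)
  gy <- matrix(rep((seq_len(H) - 0.5) / H, times = W), H, W)
  field <- matrix(0, H, W)
  for (b in blobs) {
    d2 <- (gx - b$center[1])^2 + (gy - b$center[2])^2
    field <- field + b$amplitude * exp(-d2 / (2 * b$sigma^2))
  }
  pmin(pmax(field, 0), 1)
}

#' @describeIn makeActivationField seeded random blob specifications
#'   (uniform centers, sigma in [0.05, 0.2], amplitude in [0.3, 1]).
#' @param n number of blobs.
#' @param seed integer seed.
#' @export
randomBlobs <- function(n, seed = NULL) {
  .with_seed(seed, lapply(seq_len(n), function(i)
    list(center = stats::runif(2),
         sigma = stats::runif(1, 0.05, 0.2),
         amplitude = stats::runif(1, 0.3, 1))))
}

#' Jet-style colormap hitting the four reference anchors
#'
#' Piecewise-linear breakpoints 0 -> blue (0,0,255), 1/3 -> green (0,255,0),
#' 2/3 -> yellow (255,255,0), 1 -> red (255,0,0). The breakpoints coincide
#' with the default [ReferenceScheme-class] anchors, so family assignment at
#' breakpoint intensities is analytic.
#'
#' @return list with \code{breaks} (increasing in [0, 1]) and \code{colors}
#'   (n x 3 sRGB matrix, 0-255).
#' @export
jetColormap <- function() {
  list(breaks = c(0, 1 / 3, 2 / 3, 1),
       colors = rbind(c(0, 0, 255), c(0, 255, 0),
                      c(255, 255, 0), c(255, 0, 0)))
}

# Scalar/vector piecewise-linear colormap lookup; returns n x 3 sRGB 0-255
# (rounded to 8-bit levels, as a rendered PNG would store them).
.colormap_rgb <- function(u, cmap) {
  u <- pmin(pmax(u, cmap$breaks[1]), cmap$breaks[length(cmap$breaks)])
  out <- vapply(1:3, function(ch)
    stats::approx(cmap$breaks, cmap$colors[, ch], xout = u)$y,
    numeric(length(u)))
  round(matrix(out, ncol = 3))
}

#' Render an activation field through a colormap
#'
#' @param field H x W matrix in [0, 1] (see [makeActivationField()]).
#' @param cmap colormap spec (see [jetColormap()]); breakpoints must be
#'   strictly increasing and span [0, 1].
#' @return H x W x 3 image array in [0, 1], quantized to 8-bit levels.
#' @export
applyColormap <- function(field, cmap = jetColormap()) {
  if (any(diff(cmap$breaks) <= 0) || cmap$breaks[1] != 0 ||
      cmap$breaks[length(cmap$breaks)] != 1)
    stop("colormap breakpoints must increase strictly and span [0, 1]")
  rgb <- .colormap_rgb(as.vector(field), cmap) / 255
  array(c(rgb[, 1], rgb[, 2], rgb[, 3]), c(dim(field), 3))
}

#' Independent per-pixel ATW oracle
#'
#' Recomputes the ATW of a rendered activation field by a deliberately plain
#' double loop over pixels — colormap lookup, Lab conversion, scalar
#' CIEDE2000 against each anchor, hotter-family tie-break, band
#' interpolation, arithmetic mean — with none of the vectorized machinery of
#' [computeATW()]. Used to verify the main path.
#'
#' @param field H x W activation matrix in [0, 1].
#' @param cmap colormap spec.
#' @param scheme a [ReferenceScheme-class].
#' @param mask optional logical H x W mask.
#' @return the oracle ATW value.
#' @export
expectedATW <- function(field, cmap = jetColormap(),
                        scheme = defaultScheme(), mask = NULL) {
  H <- nrow(field); W <- ncol(field)
  if (is.null(mask)) mask <- matrix(TRUE, H, W)
  ord <- order(scheme@hotRank)
  total <- 0; n <- 0
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      if (!mask[i, j]) next
      rgb <- .colormap_rgb(field[i, j], cmap)
      lab <- srgbToLab(as.numeric(rgb))
      dists <- numeric(4)
      for (f in 1:4)
        dists[f] <- ciede2000(lab, scheme@anchorsLab[f, ])
      best <- ord[1]
      for (f in ord)                      # hot -> cold: ties keep hotter
        if (dists[f] < dists[best] - 1e-9) best <- f
      lo <- scheme@bands[best, 1]; hi <- scheme@bands[best, 2]
      pos <- match(best, ord)
      if (pos == 4L) w <- hi
      else {
        dn <- dists[ord[pos + 1L]]
        w <- hi - (hi - lo) * dists[best] / (dists[best] + dn)
        w <- min(max(w, lo), hi)
      }
      total <- total + w
      n <- n + 1
    }
  }
  if (n == 0) stop("empty mask")
  total / n
}

#' Synthetic detection scenario with prescribed outcome
#'
#' Places \code{nGt} ground-truth boxes at the centers of distinct cells of
#' a regular grid (so distinct ground truths never overlap), emits jittered
#' detections for \code{nGt - nMissed} of them (jitter capped so the IoU
#' with the parent box stays comfortably above 0.5) and \code{nFalse} false
#' detections in otherwise-empty cells (IoU 0 with every ground truth). By
#' construction, [matchDetections()] at threshold 0.5 yields exactly
#' \code{tp = nGt - nMissed}, \code{fp = nFalse}, \code{fn = nMissed}.
#'
#' @param nGt number of ground-truth boxes.
#' @param nMissed number of ground truths left undetected.
#' @param nFalse number of spurious detections.
#' @param iouNoise jitter intensity in [0, 1]; scales the center offset of
#'   matched detections (0 = exact copies).
#' @param seed integer seed.
#' @return list with \code{gts} and \code{dets} box data.frames.
#' @export
makeDetectionScenario <- function(nGt, nMissed = 0, nFalse = 0,
                                  iouNoise = 0.5, seed = 1) {
  if (nMissed > nGt) stop("cannot miss more targets than exist")
  if (iouNoise < 0 || iouNoise > 1) stop("iouNoise must lie in [0, 1]")
  g <- ceiling(sqrt(nGt + nFalse))
  cell <- 1 / g
  bw <- 0.4 * cell                       # box side; gaps guarantee IoU 0
  .with_seed(seed, {
    cells <- sample.int(g * g, nGt + nFalse)
    ccx <- ((cells - 1) %% g + 0.5) * cell
    ccy <- ((cells - 1) %/% g + 0.5) * cell
    gts <- yoloBoxes(rep(0L, nGt), ccx[seq_len(nGt)], ccy[seq_len(nGt)],
                     rep(bw, nGt), rep(bw, nGt))
    hit <- if (nGt) sort(sample.int(nGt, nGt - nMissed)) else integer()
    maxShift <- 0.1 * bw * iouNoise      # keeps IoU >= ~0.67 with parent
    detList <- list()
    if (length(hit)) {
      dx <- stats::runif(length(hit), -maxShift, maxShift)
      dy <- stats::runif(length(hit), -maxShift, maxShift)
      detList$tp <- data.frame(class_id = 0L,
                               cx = gts$cx[hit] + dx, cy = gts$cy[hit] + dy,
                               w = bw, h = bw,
                               conf = stats::runif(length(hit), 0.5, 1))
    }
    if (nFalse) {
      idx <- nGt + seq_len(nFalse)
      detList$fp <- data.frame(class_id = 0L, cx = ccx[idx], cy = ccy[idx],
                               w = bw, h = bw,
                               conf = stats::runif(nFalse, 0.1, 0.9))
    }
    dets <- if (length(detList)) do.call(rbind, detList)
            else detectionBoxes(integer(), numeric(), numeric(), numeric(),
                                numeric(), numeric())
    rownames(dets) <- NULL
    list(gts = gts, dets = .check_boxes(dets, conf = TRUE))
  })
}

#' Overlay a heat map on a background image
#'
#' Alpha-blends a rendered heat map over a synthetic "field photo" and
#' returns the known heat-region mask, for exercising the segmentation
#' strategies against ground truth.
#'
#' @param heatmap H x W x 3 heat-map array in [0, 1].
#' @param background H x W x 3 background array in [0, 1].
#' @param alpha blend weight of the heat map in [0, 1] (1 = heat map only).
#' @param heatMask logical H x W matrix marking true heat pixels;
#'   default marks every pixel.
#' @return list with \code{image} and \code{mask}.
#' @export
renderOverlay <- function(heatmap, background, alpha, heatMask = NULL) {
  heatmap <- .as_rgb_array(heatmap)
  background <- .as_rgb_array(background)
  if (!identical(dim(heatmap), dim(background)))
    stop("heatmap and background shapes must match")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (is.null(heatMask))
    heatMask <- matrix(TRUE, dim(heatmap)[1], dim(heatmap)[2])
  list(image = alpha * heatmap + (1 - alpha) * background, mask = heatMask)
}
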