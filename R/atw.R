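# The ATW (Average Temperature Weight) statistic: every foreground pixel of a
# false-color class-activation map is assigned to the reference family whose
# anchor is nearest in CIEDE2000, given a weight interpolated within the
# family's temperature band, and the weights are averaged over the mask.

.TIE_EPS <- 1e-9

.as_rgb_array <- function(img) {
  if (is.matrix(img)) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] < 3L)
    stop("image must be an H x W x 3 array")
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  if (any(!is.finite(img)) || min(img) < 0 || max(img) > 1)
    stop("image values must lie in [0, 1]")
  img
}

# Flatten an H x W x 3 [0,1] array to an N x 3 matrix of 8-bit sRGB values,
# pixels in R's column-major order (consistent with as.vector on the mask).
.pixel_matrix <- function(img) {
  img <- .as_rgb_array(img)
  round(255 * cbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
                    as.vector(img[, , 3])))
}

#' Read or write an RGB raster image
#'
#' Thin wrappers over the png package. Images are represented throughout as
#' numeric H x W x 3 arrays with values in [0, 1]; gray and RGBA rasters are
#' promoted/truncated to 3 channels on read.
#'
#' @param path PNG file path.
#' @return \code{readImageRGB}: an H x W x 3 array in [0, 1].
#' @export
readImageRGB <- function(path) {
  img <- png::readPNG(path)
  .as_rgb_array(img)
}

#' @rdname readImageRGB
#' @param img H x W x 3 array in [0, 1].
#' @export
writeImageRGB <- function(img, path) {
  png::writePNG(.as_rgb_array(img), path)
  invisible(path)
}

#' Segment the foreground of a heat map
#'
#' Restricts the ATW average to pixels carrying thermal signal. Three
#' strategies are offered because the upstream segmentation rule for
#' published heat maps is tool-specific: \code{"full"} keeps every pixel
#' (the default used by [computeATW()] when no mask is given),
#' \code{"external"} adopts a caller-supplied mask (e.g. from the detector's
#' box or an overlay alpha channel), and \code{"anchor_proximity"} keeps
#' pixels whose minimum CIEDE2000 distance to any of the four scheme anchors
#' is at most \code{tau}, i.e. pixels that look like part of the colormap
#' rather than background imagery.
#'
#' @param img H x W x 3 array in [0, 1].
#' @param strategy one of \code{"full"}, \code{"external"},
#'   \code{"anchor_proximity"}.
#' @param mask logical H x W matrix, required for \code{"external"}.
#' @param tau CIEDE2000 radius for \code{"anchor_proximity"}; default 30.
#' @param scheme a [ReferenceScheme-class].
#' @return logical H x W matrix with at least one \code{TRUE} pixel.
#' @export
segmentForeground <- function(img,
                              strategy = c("full", "external",
                                           "anchor_proximity"),
                              mask = NULL, tau = 30,
                              scheme = defaultScheme()) {
  img <- .as_rgb_array(img)
  strategy <- match.arg(strategy)
  hw <- dim(img)[1:2]
  out <- switch(strategy,
    full = matrix(TRUE, hw[1], hw[2]),
    external = {
      if (is.null(mask)) stop("strategy 'external' requires a mask")
      if (!is.logical(mask) || !identical(dim(mask), hw))
        stop("mask must be a logical matrix matching the image shape")
      mask
    },
    anchor_proximity = {
      lab <- srgbToLab(.pixel_matrix(img))
      d <- .anchor_distances(lab, scheme)
      dmin <- pmin(d[, 1], d[, 2], d[, 3], d[, 4])
      matrix(dmin <= tau, hw[1], hw[2])
    }
  )
  if (!any(out))
    stop("empty foreground: ATW is undefined for N = 0")
  out
}

# N x 4 CIEDE2000 distances from Lab pixels to the four scheme anchors.
.anchor_distances <- function(lab, scheme) {
  d <- vapply(seq_len(4), function(i)
    ciede2000(lab, scheme@anchorsLab[i, , drop = FALSE]),
    numeric(nrow(lab)))
  matrix(d, ncol = 4, dimnames = list(NULL, scheme@familyNames))
}

# Family index per pixel: nearest anchor, ties (within .TIE_EPS) resolved in
# favor of the hotter family (lower hotRank).
.select_family <- function(d, scheme) {
  dmin <- pmin(d[, 1], d[, 2], d[, 3], d[, 4])
  elig <- d <= dmin + .TIE_EPS
  penal <- matrix(rep(scheme@hotRank, each = nrow(d)), ncol = 4)
  penal[!elig] <- Inf
  max.col(-penal, ties.method = "first")
}

#' Nearest reference family of a pixel
#'
#' Implements the 0/1 nearest-color selector of the ATW formula: each pixel
#' belongs to exactly one family, the one whose anchor minimizes the
#' CIEDE2000 distance. A pixel equidistant (within 1e-9) from two anchors is
#' assigned to the hotter family.
#'
#' @param lab a length-3 Lab vector or n x 3 matrix of pixel colors.
#' @param scheme a [ReferenceScheme-class].
#' @return list with \code{family} (character vector) and \code{distances}
#'   (n x 4 matrix of CIEDE2000 distances to the anchors).
#' @export
nearestFamily <- function(lab, scheme = defaultScheme()) {
  lab <- .as_lab_matrix(lab)
  d <- .anchor_distances(lab, scheme)
  idx <- .select_family(d, scheme)
  list(family = scheme@familyNames[idx], distances = d)
}

# Interpolated temperature weight given precomputed distances + family index.
.weights_from_distances <- function(d, famIdx, scheme) {
  ord <- order(scheme@hotRank)           # family indices, hot -> cold
  coolerOf <- rep(NA_integer_, 4)
  coolerOf[ord[-4]] <- ord[-1]
  lo <- scheme@bands[famIdx, 1]
  hi <- scheme@bands[famIdx, 2]
  nxt <- coolerOf[famIdx]
  df <- d[cbind(seq_along(famIdx), famIdx)]
  hasNext <- !is.na(nxt)
  w <- hi
  if (any(hasNext)) {
    i <- which(hasNext)
    dn <- d[cbind(i, nxt[i])]
    tot <- df[i] + dn
    ratio <- ifelse(tot > 0, df[i] / tot, 0)  # tot = 0 impossible: anchors distinct
    w[i] <- hi[i] - (hi[i] - lo[i]) * ratio
  }
  unname(pmin(pmax(w, lo), hi))
}

#' Temperature weight of a pixel
#'
#' The dynamic interpolation within the selected family's band: for a pixel
#' assigned to family f with band \code{[lo, hi]}, anchor distance
#' \code{d_f} and distance \code{d_next} to the adjacent cooler anchor
#' (red to yellow, yellow to green, green to blue),
#' \deqn{w = hi - (hi - lo) \cdot d_f / (d_f + d_{next}),}
#' clamped to \code{[lo, hi]}. The weight equals \code{hi} at the anchor and
#' decays toward \code{lo} as the pixel drifts toward the cooler family. The
#' coolest family has no cooler neighbor and scores its band's upper bound
#' (0 for the default blue band).
#'
#' @inheritParams nearestFamily
#' @return numeric vector of weights in [0, 1].
#' @export
pixelWeight <- function(lab, scheme = defaultScheme()) {
  lab <- .as_lab_matrix(lab)
  d <- .anchor_distances(lab, scheme)
  famIdx <- .select_family(d, scheme)
  .weights_from_distances(d, famIdx, scheme)
}

#' Compute the Average Temperature Weight of a heat map
#'
#' The ATW of a false-color class-activation map: the mean, over foreground
#' pixels, of the temperature weight obtained by nearest-reference-family
#' assignment (CIEDE2000 in CIELAB) and within-family interpolation. Higher
#' ATW means the map runs hotter, i.e. the detector activates more strongly
#' on the imaged region.
#'
#' @param img H x W x 3 array in [0, 1] (e.g. from [readImageRGB()] or
#'   [applyColormap()]).
#' @param mask logical H x W foreground mask; \code{NULL} keeps all pixels.
#'   See [segmentForeground()].
#' @param scheme a [ReferenceScheme-class].
#' @return an [ATWResult-class].
#' @examples
#' img <- array(0, c(4, 4, 3)); img[, , 1] <- 1   # uniform anchor red
#' atw(computeATW(img))                            # 1.0
#' @export
computeATW <- function(img, mask = NULL, scheme = defaultScheme()) {
  img <- .as_rgb_array(img)
  if (is.null(mask)) mask <- matrix(TRUE, dim(img)[1], dim(img)[2])
  if (!is.logical(mask) || !identical(dim(mask), dim(img)[1:2]))
    stop("mask must be a logical matrix matching the image shape")
  keep <- as.vector(mask)
  if (!any(keep)) stop("empty foreground: ATW is undefined for N = 0")
  px <- .pixel_matrix(img)[keep, , drop = FALSE]
  lab <- srgbToLab(px)
  d <- .anchor_distances(lab, scheme)
  famIdx <- .select_family(d, scheme)
  w <- .weights_from_distances(d, famIdx, scheme)

  counts <- tabulate(famIdx, nbins = 4L)
  means <- vapply(seq_len(4), function(i)
    if (counts[i] > 0L) mean(w[famIdx == i]) else NA_real_, numeric(1))
  new("ATWResult",
      atw = mean(w),
      nForeground = as.integer(sum(keep)),
      familyCounts = stats::setNames(as.integer(counts), scheme@familyNames),
      familyMeanWeights = stats::setNames(means, scheme@familyNames))
}

#' @describeIn computeATW the ATW value of a result.
#' @param x an [ATWResult-class].
#' @export
atw <- function(x) x@atw

#' @describeIn computeATW foreground pixel count N.
#' @export
nForeground <- function(x) x@nForeground

#' @describeIn computeATW per-family foreground pixel counts.
#' @export
familyCounts <- function(x) x@familyCounts

#' @describeIn computeATW per-family mean temperature weights.
#' @export
familyMeanWeights <- function(x) x@familyMeanWeights

setMethod("show", "ATWResult", function(object) {
  cat(sprintf("ATWResult: ATW = %.4f over %d foreground pixels\n",
              object@atw, object@nForeground))
  df <- data.frame(
    family = names(object@familyCounts),
    pixels = as.integer(object@familyCounts),
    meanWeight = round(object@familyMeanWeights, 4)
  )
  print(df, row.names = FALSE)
})

#' Compare two ATW results
#'
#' Reports the improvement of one heat map over another as an absolute
#' difference in percentage points and as a relative enhancement in percent
#' of the baseline (the two figures a model comparison quotes side by side).
#'
#' @param baseline,improved [ATWResult-class] objects or bare ATW values in
#'   [0, 1].
#' @return list with \code{deltaPp} (percentage points,
#'   \code{100 * (improved - baseline)}) and \code{relativePct}
#'   (\code{100 * (improved - baseline) / baseline}; \code{NA} when the
#'   baseline is 0, where relative enhancement is undefined).
#' @export
compareATW <- function(baseline, improved) {
  val <- function(z) if (is(z, "ATWResult")) z@atw else as.numeric(z)
  b <- val(baseline); i <- val(improved)
  if (length(b) != 1L || length(i) != 1L || !is.finite(b) || !is.finite(i))
    stop("baseline and improved must be single finite ATW values")
  list(
    deltaPp = 100 * (i - b),
    relativePct = if (b > 0) 100 * (i - b) / b else NA_real_
  )
}
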