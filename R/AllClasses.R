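#' @import methods
NULL

#' ReferenceScheme: the four anchor colors and their temperature-weight bands
#'
#' A \code{ReferenceScheme} holds the ordered set of reference colors that the
#' ATW statistic compares every heat-map pixel against: an sRGB anchor per
#' family (with its cached CIELAB coordinates), the temperature-weight band
#' \code{[wLo, wHi]} spanned within the family, and the hotness rank used to
#' break ties when a pixel is equidistant from two anchors (rank 0 = hottest).
#'
#' The default scheme assigns red the band [0.8, 1.0], yellow [0.6, 0.8],
#' green [0.4, 0.6] and blue the constant weight 0 (a degenerate [0, 0] band).
#'
#' @slot familyNames character(4), family labels ordered hot to cold.
#' @slot anchorsRgb 4 x 3 numeric matrix of sRGB anchors, channels in 0-255.
#' @slot anchorsLab 4 x 3 numeric matrix of the anchors converted to CIELAB.
#' @slot bands 4 x 2 numeric matrix of weight bands, columns \code{wLo, wHi}.
#' @slot hotRank integer(4), a permutation of 0:3; 0 is the hottest family.
#'
#' @seealso [referenceScheme()], [defaultScheme()], [computeATW()]
#' @export
setClass("ReferenceScheme",
  representation(
    familyNames = "character",
    anchorsRgb = "matrix",
    anchorsLab = "matrix",
    bands = "matrix",
    hotRank = "integer"
  )
)

setValidity("ReferenceScheme", function(object) {
  msg <- character()
  if (length(object@familyNames) != 4L || anyDuplicated(object@familyNames))
    msg <- c(msg, "exactly 4 distinct family names are required")
  if (!identical(dim(object@anchorsRgb), c(4L, 3L)))
    msg <- c(msg, "anchorsRgb must be a 4 x 3 matrix")
  else if (any(object@anchorsRgb < 0) || any(object@anchorsRgb > 255))
    msg <- c(msg, "anchor channels must lie in [0, 255]")
  else if (anyDuplicated(object@anchorsRgb, MARGIN = 1))
    msg <- c(msg, "anchors must be pairwise distinct")
  if (!identical(dim(object@anchorsLab), c(4L, 3L)))
    msg <- c(msg, "anchorsLab must be a 4 x 3 matrix")
  if (!identical(dim(object@bands), c(4L, 2L)))
    msg <- c(msg, "bands must be a 4 x 2 matrix")
  else if (any(object@bands < 0) || any(object@bands > 1) ||
           any(object@bands[, 1] > object@bands[, 2]))
    msg <- c(msg, "each band must satisfy 0 <= wLo <= wHi <= 1")
  if (!identical(sort(object@hotRank), 0:3))
    msg <- c(msg, "hotRank must be a permutation of 0:3")
  if (length(msg)) msg else TRUE
})

#' ATWResult: the Average Temperature Weight of one heat map
#'
#' Returned by [computeATW()]. Stores the ATW value (mean temperature weight
#' over foreground pixels), the number of foreground pixels N, and the
#' per-family breakdown: how many pixels each reference family claimed and
#' their mean weight.
#'
#' @slot atw numeric(1) in [0, 1].
#' @slot nForeground integer(1), the N of the ATW average.
#' @slot familyCounts named integer(4), foreground pixels per family.
#' @slot familyMeanWeights named numeric(4), mean weight per family
#'   (\code{NA} for a family with no pixels).
#'
#' @seealso [computeATW()], [compareATW()]
#' @export
setClass("ATWResult",
  representation(
    atw = "numeric",
    nForeground = "integer",
    familyCounts = "integer",
    familyMeanWeights = "numeric"
  )
)

setValidity("ATWResult", function(object) {
  msg <- character()
  if (length(object@atw) != 1L || is.na(object@atw) ||
      object@atw < 0 || object@atw > 1)
    msg <- c(msg, "atw must be a single value in [0, 1]")
  if (length(object@nForeground) != 1L || object@nForeground < 1L)
    msg <- c(msg, "nForeground must be a positive count")
  if (sum(object@familyCounts) != object@nForeground)
    msg <- c(msg, "family counts must sum to nForeground")
  occ <- object@familyCounts > 0L
  if (any(occ)) {
    recon <- sum(object@familyCounts[occ] * object@familyMeanWeights[occ]) /
      object@nForeground
    if (abs(recon - object@atw) > 1e-9)
      msg <- c(msg, "atw must equal the count-weighted mean of family means")
  }
  if (length(msg)) msg else TRUE
})

#' EvalCounts: true/false positive and false negative bookkeeping
#'
#' @slot tp,fp,fn non-negative integer counts. \code{tp + fn} equals the
#'   number of ground-truth boxes and \code{tp + fp} the number of detections
#'   in the scenario they were derived from.
#'
#' @seealso [matchDetections()], [fieldCounts()]
#' @export
setClass("EvalCounts",
  representation(tp = "integer", fp = "integer", fn = "integer")
)

setValidity("EvalCounts", function(object) {
  counts <- c(object@tp, object@fp, object@fn)
  if (length(counts) != 3L || any(is.na(counts)) || any(counts < 0L))
    "tp, fp and fn must be single non-negative integers"
  else TRUE
})
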