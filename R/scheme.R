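#' Construct a ReferenceScheme
#'
#' @param anchorsRgb 4 x 3 matrix of sRGB anchors (rows ordered hot to cold),
#'   channels in 0-255.
#' @param bands 4 x 2 matrix of temperature-weight bands \code{[wLo, wHi]}.
#' @param familyNames character(4) family labels.
#' @param hotRank integer(4) permutation of 0:3; defaults to row order.
#' @return a validated [ReferenceScheme-class] object with cached Lab anchors.
#' @seealso [defaultScheme()]
#' @export
referenceScheme <- function(anchorsRgb, bands,
                            familyNames = c("red", "yellow", "green", "blue"),
                            hotRank = 0:3) {
  anchorsRgb <- as.matrix(anchorsRgb)
  bands <- as.matrix(bands)
  storage.mode(anchorsRgb) <- "double"
  storage.mode(bands) <- "double"
  rownames(anchorsRgb) <- rownames(bands) <- familyNames
  colnames(bands) <- c("wLo", "wHi")
  new("ReferenceScheme",
      familyNames = familyNames,
      anchorsRgb = anchorsRgb,
      anchorsLab = srgbToLab(anchorsRgb),
      bands = bands,
      hotRank = as.integer(hotRank))
}

#' The default four-family reference scheme
#'
#' Anchors are the pure sRGB primaries/secondary hit by a jet-style colormap:
#' red (255,0,0), yellow (255,255,0), green (0,255,0), blue (0,0,255), with
#' temperature-weight bands red [0.8, 1.0], yellow [0.6, 0.8], green
#' [0.4, 0.6] and blue fixed at 0.
#'
#' @return a [ReferenceScheme-class].
#' @export
defaultScheme <- function() {
  referenceScheme(
    anchorsRgb = rbind(c(255, 0, 0), c(255, 255, 0), c(0, 255, 0), c(0, 0, 255)),
    bands = rbind(c(0.8, 1.0), c(0.6, 0.8), c(0.4, 0.6), c(0.0, 0.0))
  )
}

#' @describeIn referenceScheme family names, ordered hot to cold.
#' @param x,object a \code{ReferenceScheme}.
#' @export
familyNames <- function(x) x@familyNames

#' @describeIn referenceScheme sRGB anchor matrix (4 x 3, 0-255).
#' @export
anchorsRgb <- function(x) x@anchorsRgb

#' @describeIn referenceScheme cached CIELAB anchor matrix.
#' @export
anchorsLab <- function(x) x@anchorsLab

#' @describeIn referenceScheme weight-band matrix (4 x 2).
#' @export
schemeBands <- function(x) x@bands

#' @describeIn referenceScheme hotness ranks (0 = hottest).
#' @export
hotRanks <- function(x) stats::setNames(x@hotRank, x@familyNames)

setMethod("show", "ReferenceScheme", function(object) {
  cat("ReferenceScheme with", length(object@familyNames), "families\n")
  df <- data.frame(
    family = object@familyNames,
    r = object@anchorsRgb[, 1], g = object@anchorsRgb[, 2],
    b = object@anchorsRgb[, 3],
    wLo = object@bands[, 1], wHi = object@bands[, 2],
    hotRank = object@hotRank
  )
  print(df, row.names = FALSE)
})

#' Read or write a reference scheme as YAML
#'
#' The file lists, per family, the sRGB anchor and the weight band, e.g.:
#' \preformatted{
#' families:
#'   - name: red
#'     anchor: [255, 0, 0]
#'     band: [0.8, 1.0]
#' }
#' Families are taken in file order (hot to cold) unless an explicit
#' \code{hot_rank} is given per family.
#'
#' @param path YAML file path.
#' @return [ReferenceScheme-class] for the reader; invisibly \code{path} for
#'   the writer.
#' @export
readSchemeYaml <- function(path) {
  spec <- yaml::read_yaml(path)
  fams <- spec$families
  if (is.null(fams) || length(fams) != 4L)
    stop("scheme YAML must define exactly 4 families")
  nm <- vapply(fams, function(f) as.character(f$name), character(1))
  anchors <- t(vapply(fams, function(f) as.numeric(f$anchor), numeric(3)))
  bands <- t(vapply(fams, function(f) as.numeric(f$band), numeric(2)))
  ranks <- vapply(fams, function(f)
    if (is.null(f$hot_rank)) NA_integer_ else as.integer(f$hot_rank),
    integer(1))
  if (all(is.na(ranks))) ranks <- 0:3
  referenceScheme(anchors, bands, familyNames = nm, hotRank = ranks)
}

#' @rdname readSchemeYaml
#' @param scheme a [ReferenceScheme-class] to serialize.
#' @export
writeSchemeYaml <- function(scheme, path) {
  fams <- lapply(seq_len(4), function(i) list(
    name = scheme@familyNames[i],
    anchor = as.numeric(scheme@anchorsRgb[i, ]),
    band = as.numeric(scheme@bands[i, ]),
    hot_rank = scheme@hotRank[i]
  ))
  yaml::write_yaml(list(families = fams), path)
  invisible(path)
}
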