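# sRGB -> CIELAB conversion and the CIEDE2000 color difference.
# Conventions fixed here and documented for auditability:
#   * sRGB inverse companding per IEC 61966-2-1,
#   * D65 reference white, 2 degree standard observer,
#   * CIEDE2000 with parametric factors kL = kC = kH = 1 unless overridden.

# sRGB (linear) -> XYZ matrix, D65 white, 2 degree observer.
.SRGB_TO_XYZ <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041
), nrow = 3, byrow = TRUE)

# D65 reference white tristimulus values (Y normalized to 1).
.WHITE_D65 <- c(X = 0.95047, Y = 1.00000, Z = 1.08883)

.as_rgb_matrix <- function(rgb) {
  if (is.null(dim(rgb))) rgb <- matrix(rgb, ncol = 3, byrow = TRUE)
  if (ncol(rgb) != 3L)
    stop("rgb input must have 3 channels (r, g, b)")
  if (any(!is.finite(rgb)) || any(rgb < 0) || any(rgb > 255))
    stop("rgb channels must be finite values in [0, 255]")
  rgb
}

#' Convert sRGB colors to CIELAB
#'
#' Applies the standard chain: sRGB inverse companding (IEC 61966-2-1),
#' linear RGB to XYZ under the D65 white point and 2 degree observer, then
#' XYZ to CIELAB. sRGB white (255, 255, 255) maps exactly to
#' \code{L = 100, a = 0, b = 0} because the conversion matrix rows sum to the
#' D65 white.
#'
#' @param rgb a length-3 vector \code{c(r, g, b)} or an n x 3 matrix of sRGB
#'   channel values in [0, 255] (fractional values are allowed; 8-bit images
#'   supply integers).
#' @return an n x 3 matrix with columns \code{L, a, b} (a 1 x 3 matrix for a
#'   single color).
#' @examples
#' srgbToLab(c(255, 0, 0))
#' @export
srgbToLab <- function(rgb) {
  rgb <- .as_rgb_matrix(rgb) / 255
  lin <- ifelse(rgb <= 0.04045, rgb / 12.92, ((rgb + 0.055) / 1.055)^2.4)
  xyz <- lin %*% t(.SRGB_TO_XYZ)
  xyz <- sweep(xyz, 2, .WHITE_D65, "/")
  eps <- (6 / 29)^3
  f <- ifelse(xyz > eps, xyz^(1 / 3), xyz / (3 * (6 / 29)^2) + 4 / 29)
  out <- cbind(
    L = 116 * f[, 2] - 16,
    a = 500 * (f[, 1] - f[, 2]),
    b = 200 * (f[, 2] - f[, 3])
  )
  out
}

.as_lab_matrix <- function(lab, arg = "lab") {
  if (is.null(dim(lab))) lab <- matrix(lab, ncol = 3, byrow = TRUE)
  if (ncol(lab) != 3L)
    stop(sprintf("%s must have 3 columns (L, a, b)", arg))
  if (any(!is.finite(lab)))
    stop(sprintf("%s contains non-finite values", arg))
  lab
}

#' CIEDE2000 color difference
#'
#' The CIE 2000 color-difference formula between CIELAB colors, including the
#' chroma-dependent a' rescaling, the lightness/chroma/hue weighting
#' functions, and the blue-region rotation term. Hue-angle branches follow
#' the published reference formulation. Vectorized: \code{x} and \code{y} may
#' be n x 3 matrices (recycled row-wise when one has a single row).
#'
#' @param x,y Lab colors, length-3 vectors or n x 3 matrices.
#' @param kL,kC,kH parametric weighting factors; unity by default.
#' @return numeric vector of non-negative differences, 0 iff \code{x == y}.
#' @examples
#' ciede2000(c(50, 2.6772, -79.7751), c(50, 0, -82.7485))
#' @export
ciede2000 <- function(x, y, kL = 1, kC = 1, kH = 1) {
  x <- .as_lab_matrix(x, "x")
  y <- .as_lab_matrix(y, "y")
  n <- max(nrow(x), nrow(y))
  if (nrow(x) == 1L && n > 1L) x <- x[rep(1L, n), , drop = FALSE]
  if (nrow(y) == 1L && n > 1L) y <- y[rep(1L, n), , drop = FALSE]
  if (nrow(x) != nrow(y))
    stop("x and y must have the same number of rows (or one row)")

  deg2rad <- pi / 180
  L1 <- x[, 1]; a1 <- x[, 2]; b1 <- x[, 3]
  L2 <- y[, 1]; a2 <- y[, 2]; b2 <- y[, 3]

  C1 <- sqrt(a1^2 + b1^2)
  C2 <- sqrt(a2^2 + b2^2)
  Cbar <- (C1 + C2) / 2
  G <- 0.5 * (1 - sqrt(Cbar^7 / (Cbar^7 + 25^7)))
  a1p <- (1 + G) * a1
  a2p <- (1 + G) * a2
  C1p <- sqrt(a1p^2 + b1^2)
  C2p <- sqrt(a2p^2 + b2^2)

  hp <- function(b, ap) {
    h <- atan2(b, ap) / deg2rad
    ifelse(b == 0 & ap == 0, 0, ifelse(h < 0, h + 360, h))
  }
  h1p <- hp(b1, a1p)
  h2p <- hp(b2, a2p)

  dLp <- L2 - L1
  dCp <- C2p - C1p
  dh <- h2p - h1p
  dhp <- ifelse(C1p * C2p == 0, 0,
         ifelse(abs(dh) <= 180, dh,
         ifelse(dh > 180, dh - 360, dh + 360)))
  dHp <- 2 * sqrt(C1p * C2p) * sin(dhp / 2 * deg2rad)

  Lbp <- (L1 + L2) / 2
  Cbp <- (C1p + C2p) / 2
  hsum <- h1p + h2p
  hbp <- ifelse(C1p * C2p == 0, hsum,
         ifelse(abs(h1p - h2p) <= 180, hsum / 2,
         ifelse(hsum < 360, (hsum + 360) / 2, (hsum - 360) / 2)))

  Tt <- 1 - 0.17 * cos((hbp - 30) * deg2rad) +
        0.24 * cos(2 * hbp * deg2rad) +
        0.32 * cos((3 * hbp + 6) * deg2rad) -
        0.20 * cos((4 * hbp - 63) * deg2rad)
  dTheta <- 30 * exp(-((hbp - 275) / 25)^2)
  RC <- 2 * sqrt(Cbp^7 / (Cbp^7 + 25^7))
  SL <- 1 + 0.015 * (Lbp - 50)^2 / sqrt(20 + (Lbp - 50)^2)
  SC <- 1 + 0.045 * Cbp
  SH <- 1 + 0.015 * Cbp * Tt
  RT <- -sin(2 * dTheta * deg2rad) * RC

  tL <- dLp / (kL * SL)
  tC <- dCp / (kC * SC)
  tH <- dHp / (kH * SH)
  sqrt(pmax(tL^2 + tC^2 + tH^2 + RT * tC * tH, 0))
}
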