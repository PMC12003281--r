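# Closed-form model arithmetic: GhostConv compute/parameter savings ratios
# and the cosine-annealing learning-rate schedule.

#' GhostConv compute and parameter savings ratios
#'
#' A Ghost convolution produces \code{n/s} feature maps by ordinary k x k
#' convolution and derives the remaining \code{(s-1) n/s} maps by cheap
#' d x d per-channel linear transforms. Relative to a standard convolution
#' with \code{n} kernels over \code{c} input channels, the speedup
#' (FLOPs ratio \code{rs}) and compression (parameter ratio \code{rc}) are
#' \deqn{r_s = \frac{c k^2}{\frac{1}{s} c k^2 + \frac{s-1}{s} d^2}, \qquad
#'       r_c = \frac{n c k^2}{\frac{n}{s} c k^2 + (s-1)\frac{n}{s} d^2},}
#' both approaching \code{s} as \code{c} grows with \code{d} of the order of
#' \code{k}. The exact values are returned alongside the asymptote so the
#' quality of the "approximately s" simplification is visible; with
#' \code{d = k} the parameter ratio collapses to \code{s c / (s + c - 1)}.
#'
#' The raw (unsimplified) FLOP/parameter counts are also returned when the
#' output spatial size \code{HW} is supplied, for checking the algebraic
#' reduction.
#'
#' @param c input channels.
#' @param k standard convolution kernel size.
#' @param d linear-transform kernel size (default \code{k}).
#' @param s number of transformations per intrinsic map (>= 1; \code{s = 1}
#'   recovers standard convolution, ratio 1).
#' @param n number of output kernels (needed only for the raw counts;
#'   cancels from both ratios).
#' @param HW output spatial size \code{H * W} (raw FLOP counts only).
#' @return list with \code{rs}, \code{rc}, \code{approx = s}, and (when
#'   \code{n} and \code{HW} are given) \code{flopsStandard},
#'   \code{flopsGhost}, \code{paramsStandard}, \code{paramsGhost}.
#' @examples
#' ghostRatios(c = 16, k = 3, s = 2)   # rs = rc = 288/153
#' @export
ghostRatios <- function(c, k, d = k, s, n = NULL, HW = NULL) {
  if (any(c(c, k, d, s) <= 0)) stop("all dimensions must be positive")
  if (s != round(s) || s < 1) stop("s must be an integer >= 1")
  rs <- (c * k^2) / (c * k^2 / s + (s - 1) / s * d^2)
  rc <- rs                                # n cancels from the exact form
  out <- list(rs = rs, rc = rc, approx = s)
  if (!is.null(n) && !is.null(HW)) {
    if (n %% s != 0) stop("the exact form requires s to divide n")
    out$flopsStandard <- n * HW * k^2 * c
    out$flopsGhost <- (n / s) * HW * k^2 * c + (s - 1) * (n / s) * HW * d^2
    out$paramsStandard <- n * c * k^2
    out$paramsGhost <- (n / s) * c * k^2 + (s - 1) * (n / s) * d^2
  }
  out
}

#' Cosine-annealing learning-rate schedule
#'
#' \deqn{\eta_t = \eta_{min} + \tfrac{1}{2}(\eta_{max} - \eta_{min})
#'       \left(1 + \cos\frac{t \pi}{T_{max}}\right)}
#' The rate starts at \code{etaMax} (t = 0), reaches the midpoint
#' \code{(etaMax + etaMin)/2} at \code{t = tMax/2}, and ends at
#' \code{etaMin}; it is non-increasing throughout, decaying fastest in the
#' middle of training. \code{t} is 0-based and evaluated per epoch.
#'
#' @param t epoch index (vectorized), \code{0 <= t <= tMax}.
#' @param etaMax,etaMin maximum (initial) and minimum (final) learning
#'   rates, \code{etaMin <= etaMax}. A typical detector run uses
#'   \code{etaMax = 0.007}; \code{etaMin} has no universal default and must
#'   be chosen by the user.
#' @param tMax total number of epochs (>= 1).
#' @return learning rate(s) eta_t.
#' @export
cosineLR <- function(t, etaMax, etaMin, tMax) {
  if (etaMin > etaMax) stop("etaMin must not exceed etaMax")
  if (tMax < 1) stop("tMax must be >= 1")
  if (any(t < 0 | t > tMax)) stop("t must lie in [0, tMax]")
  etaMin + 0.5 * (etaMax - etaMin) * (1 + cos(pi * t / tMax))
}
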