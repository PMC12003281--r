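# Shared fixture builders: everything is generated in code, nothing loaded
# from disk except the published color-difference verification pairs.

# Uniform H x W image of one sRGB color (0-255 channels).
uniform_image <- function(rgb, h = 4, w = 4) {
  img <- array(0, c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- rgb[ch] / 255
  img
}

# Random RGB image quantized to 8-bit levels, reproducible under seed.
random_image <- function(h, w, seed) {
  vals <- ATWquant:::.with_seed(seed,
    round(stats::runif(h * w * 3) * 255) / 255)
  array(vals, c(h, w, 3))
}

# Random Lab colors spanning the gamut-ish box used by the reference suite.
random_lab <- function(n, seed) {
  ATWquant:::.with_seed(seed, cbind(
    L = stats::runif(n, 0, 100),
    a = stats::runif(n, -100, 100),
    b = stats::runif(n, -100, 100)
  ))
}

# Lab coordinates of the default anchors, by family name.
anchor_lab <- function(name) {
  s <- defaultScheme()
  anchorsLab(s)[match(name, familyNames(s)), ]
}

# Bisect along the Lab segment between two anchors for the equidistance
# point (d to first == d to second), returning the Lab triple on the side
# of the first (hotter) anchor.
equidistant_lab <- function(from = "red", to = "yellow", iters = 80) {
  a <- anchor_lab(from); b <- anchor_lab(to)
  gap <- function(t) {
    p <- (1 - t) * a + t * b
    ciede2000(p, a) - ciede2000(p, b)
  }
  lo <- 0; hi <- 1
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (gap(mid) <= 0) lo <- mid else hi <- mid
  }
  (1 - lo) * a + lo * b
}

# Independent scalar re-implementation of greedy confidence-ordered
# matching, used as an oracle against matchDetections(): naive loops and
# pairwise iou() only.
greedy_match_oracle <- function(dets, gts, iouThr = 0.5) {
  ord <- order(-dets$conf)
  taken <- rep(FALSE, nrow(gts))
  tp <- 0L
  for (di in ord) {
    best <- 0; bi <- 0L
    for (gi in seq_len(nrow(gts))) {
      if (taken[gi] || gts$class_id[gi] != dets$class_id[di]) next
      ov <- iou(dets[di, ], gts[gi, ])
      if (ov >= iouThr && ov > best) { best <- ov; bi <- gi }
    }
    if (bi > 0L) { taken[bi] <- TRUE; tp <- tp + 1L }
  }
  c(tp = tp, fp = nrow(dets) - tp, fn = nrow(gts) - tp)
}

# Shuffle the pixels of an image (and a mask) with one permutation.
shuffle_pixels <- function(img, mask, seed) {
  n <- prod(dim(img)[1:2])
  perm <- ATWquant:::.with_seed(seed, sample.int(n))
  out <- img
  for (ch in 1:3) {
    m <- img[, , ch]
    out[, , ch] <- matrix(as.vector(m)[perm], dim(img)[1], dim(img)[2])
  }
  list(image = out, mask = matrix(as.vector(mask)[perm], nrow(mask)))
}

verification_pairs <- function() {
  utils::read.csv(system.file("extdata", "ciede2000-pairs.csv",
                              package = "ATWquant"))
}
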