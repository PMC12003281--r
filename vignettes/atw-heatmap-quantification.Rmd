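---
title: "Average Temperature Weight: quantifying class-activation heat maps"
author: "ATWquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Average Temperature Weight: quantifying class-activation heat maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ATWquant)
```

## The problem

A detector trained to find crop seedlings can be probed with class-activation
mapping: the network's attention is rendered as a false-color heat map over
the input image, red where the evidence for the decision concentrated, blue
where it did not. Such maps are usually compared qualitatively. The Average
Temperature Weight (ATW) turns a heat map into a single number in [0, 1] so
that two models' attention on the same scene can be compared numerically.

The ATW pipeline consumes the heat map *as an image*. It does not need the
network weights, and it cannot invert the colormap back to raw activation
values; it summarizes the rendered colors themselves.

## The statistic

For each foreground pixel $i$ of the map:

1. Convert the sRGB pixel to CIELAB (sRGB companding per IEC 61966-2-1, D65
   white point, 2° observer). Lab is used because distances there track
   perceived color difference far better than RGB distances.
2. Compute the CIEDE2000 difference $d_{ic}$ to four reference anchors
   $C$ = red (255,0,0), yellow (255,255,0), green (0,255,0), blue (0,0,255).
3. Assign the pixel to the family with minimal $d_{ic}$ (the 0/1 indicator
   $I(d_{ic}, c)$; exactly one family per pixel).
4. Interpolate a temperature weight $w_{ic}$ within the family's band:
   red [0.8, 1.0], yellow [0.6, 0.8], green [0.4, 0.6], blue fixed at 0.

$$\mathrm{ATW} = \frac{1}{N} \sum_{i=1}^{N} \sum_{c \in C}
w_{ic}\, I(d_{ic}, c)$$

with $N$ the number of foreground pixels.

### The interpolation function

The band interpolation is the one genuinely open design choice: published
descriptions of such weighting say only that a "dynamic weight
interpolation" maps color difference to weight. We use a two-anchor
distance-ratio blend. For a pixel in family $f$ with band $[lo, hi]$:

$$w = hi - (hi - lo)\,\frac{d_f}{d_f + d_{next}}$$

where $d_{next}$ is the distance to the adjacent cooler anchor (red→yellow,
yellow→green, green→blue), clamped to $[lo, hi]$. This form was chosen
because it is continuous in the pixel color within a family, equals $hi$
exactly at the anchor, decays toward $lo$ as the pixel approaches the
decision boundary with the cooler family, and never leaves the printed band
limits. At the red–yellow boundary, for instance, $d_f = d_{next}$ gives
$w = 0.9$.

Consequences accepted and documented:

* **Blue is constant 0**, not a band, because the coldest family represents
  "no activation". The weight field is therefore discontinuous across the
  green/blue decision boundary (0.4 on the green side, 0 on the blue side).
  The same jump exists, smaller, at every family boundary (e.g. 0.9 → 0.8
  across red/yellow); a pixel's weight is a within-family quantity.
* **Ties go to the hotter family** (lower hot rank), deterministically, with
  a tie tolerance of 1e-9 ΔE₀₀.
* **Anchor RGB values are configurable** (`referenceScheme()`, YAML schemes
  in the CLI): published heat maps do not state their colormap's exact
  primaries, so the defaults are the pure sRGB primaries a jet-style
  colormap passes through. Because the anchors and the interpolation are
  package choices, absolute ATW values of third-party heat maps are
  reproducible *under this scheme*, not guaranteed to equal values computed
  by any other implementation.

### Color science constants

sRGB→XYZ uses the standard D65 matrix (first row 0.4124564, 0.3575761,
0.1804375, …) with white (0.95047, 1, 1.08883); CIEDE2000 uses the published
reference formulation with $k_L = k_C = k_H = 1$. The implementation is
verified against the 34 published verification pairs to 1e-4 and against an
independent reference implementation (farver) on 1000+ random Lab pairs.

## Foreground segmentation

The ATW average runs over a foreground mask. How published studies segment
"the foreground map with thermal range" is not standardized, so three
strategies are provided and none is claimed to match any particular study:

* `full` (default): every pixel. Chosen as the default because it involves
  no tunable threshold and makes results trivially comparable.
* `external`: a caller-supplied mask (e.g. the detector's box, or the known
  blend region of an overlay).
* `anchor_proximity`: keep pixels within τ ΔE₀₀ (default τ = 30) of *some*
  anchor — pixels that look like colormap output rather than background
  photography. τ = 30 sits below the distance from white/gray background
  tones to their nearest anchor (≈ 30.5 for white) while keeping blended
  colormap colors; on the package's overlay fixtures it recovers ≥ 88% of
  the true heat region.

An empty mask is an error: ATW is undefined at $N = 0$.

## Detection evaluation

The matcher is greedy and confidence-ordered at IoU ≥ 0.5 (the threshold
used throughout seedling-detection studies): detections in descending
confidence each claim the unmatched same-class ground truth of highest IoU;
confidence ties keep input order and IoU ties take the lower ground-truth
index. AP uses all-point interpolation (monotone precision envelope
integrated over recall) rather than 11-point sampling. Precision, recall
and F1 follow the standard identities; the field accounting reports
detected = (nGt − FN) + FP and miss/false rates as percentages rounded
half-up to 1 decimal, the convention of printed field-test tables (R's
banker's rounding would differ on exact halves).

## Dataset tools

Labels use the YOLO convention: normalized, center-based, origin top-left;
raster indices are 0-based at the pixel level and all geometry is computed
in normalized coordinates.

The 8:1:1 split uses sizes `val = round(0.1 N)`, `test = floor(0.1 N)`,
`train = remainder`: this is the rule consistent with the canonical sizes
2687/336/335 at N = 3358 (plain rounding of all three parts would give
2686/336/336 instead). Assignment is a seeded uniform shuffle.

Augmentations are box-aware and bit-reproducible under a fixed seed:

* **affine** — rotation/scale about the image center plus translation;
  boxes are re-derived as axis-aligned bounding boxes of their transformed
  corners (the standard convention), clipped, and dropped below a minimum
  area (default 1e-4 of the frame).
* **color distortion** — brightness/contrast in RGB, saturation/hue in HSV.
* **Gaussian noise** — i.i.d. per channel, clamped.
* **Cutout** — mean-color rectangles; labels untouched by default
  (occlusion-regularization semantics), optionally dropping boxes ≥ 80%
  covered.
* **Mosaic** — 2×2 composition about a jittered center; boxes are remapped
  into quadrant extents and dropped when clipping leaves them under 2
  canvas pixels in either dimension or under 1% of their pre-clip mapped
  area.
* **Environment presets** — direct sun, dim light, fog (contrast reduction
  plus additive white haze) and sensor noise, as pure parameterizations of
  the operators above.

The raster warps use an inverse-map nearest-neighbour sampler implemented
in the package so that raster and box geometry share one coordinate
convention exactly.

## Synthetic fixtures

The generators exist so every pipeline stage is testable with no external
data:

* Activation fields are sums of isotropic Gaussians; the jet-style
  colormap's breakpoints (0, 1/3, 2/3, 1) hit the four default anchors
  exactly, making family assignment at breakpoints analytic.
* `expectedATW()` recomputes ATW as a plain double loop per pixel — an
  independently structured oracle the vectorized path must match to 1e-9.
* Detection scenarios place ground truths at distinct cells of a regular
  grid (pairwise IoU exactly 0), jitter matched detections by at most 10%
  of a box side (IoU with the parent stays ≥ ~0.67), and put false
  detections in otherwise-empty cells, so requested (TP, FP, FN) counts are
  recovered exactly by construction.

What these fixtures do **not** emulate: real vegetation texture, colormap
anti-aliasing and JPEG artifacts, overlapping seedlings, or any particular
camera. Passing tests demonstrate the calculus is implemented correctly,
not that any detector performs at a given level on real fields.

## Model arithmetic

`ghostRatios()` returns the exact compute/parameter savings of a Ghost
convolution — $r_s = c k^2 / (\frac{1}{s} c k^2 + \frac{s-1}{s} d^2)$ and
the matching parameter ratio — alongside the asymptote $s$, so the quality
of the usual "≈ s" simplification is visible (e.g. c = 16, k = d = 3,
s = 2 gives 288/153 ≈ 1.88, not 2). `cosineLR()` implements
$\eta_t = \eta_{min} + \frac{1}{2}(\eta_{max} - \eta_{min})(1 + \cos(\pi
t / T_{max}))$ with $t$ 0-based per epoch; $\eta_{max} = 0.007$ is the
conventional initial rate for this detector family, while $\eta_{min}$ has
no universal default and is a required user input.

## Numerical choices and problem sizes

* Images are H×W×3 arrays in [0, 1]; pixel colors are quantized to 8-bit
  levels before Lab conversion, mirroring what a rendered PNG stores.
* Tie tolerance 1e-9 ΔE₀₀; oracle agreement tolerance 1e-9 on ATW; color
  verification tolerance 1e-4 ΔE₀₀.
* The test and acceptance runs use 16×16 activation fields (100 random
  fixtures for the oracle-equivalence check), ≤ 50-target detection
  scenarios for exactness sweeps, and the full 930-target scenario for the
  field-accounting figures — sizes at which every check is exact yet the
  whole suite runs in well under a minute per module on one CPU.

## Known limitations

* ATW depends on the reference scheme; absolute values from other
  implementations or other anchor choices are not directly comparable.
* The colormap cannot be inverted: two different activation fields rendered
  through different colormaps can score identically.
* The matcher is the standard greedy one; a Hungarian (optimal) matcher can
  differ on pathological overlaps.
* `anchor_proximity` segmentation assumes the background is not itself
  saturated colormap-like color.
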