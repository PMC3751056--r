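---
title: "Automatic IVOCT lumen segmentation: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic IVOCT lumen segmentation: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octlumen)
```

## The segmentation model

`octlumen` segments the blood-filled lumen of a coronary artery in
display-format time-domain IVOCT frames. The method rests on three
physical assumptions:

* **The vessel is a closed ring around the catheter.** In polar
  coordinates centered on the catheter axis the wall becomes a roughly
  horizontal band, and the lumen boundary becomes a single-valued
  function `h(theta)` — the radius of the first tissue return per
  A-line. Everything downstream (filling, height signal, gap repair)
  exploits this single-valuedness.
* **OCT carries no information behind the first tissue interface.**
  Near-infrared light is strongly scattered by the wall, so whatever
  lies radially deeper than the first return is tissue-equivalent. This
  justifies the *upward filling* step, which makes every polar column
  solid from its first foreground pixel to the maximum depth.
* **Artifacts have known geometry.** The catheter reflection ring sits
  at a fixed, known maximum radius `r_max`; alignment marks are thin
  straight lines. Both are removed or attenuated deterministically
  (blanking, 5x5 median) rather than estimated.

### Stage 1 — preprocessing

Pixels within `r_max` of the center are set to 0; a 5x5 median filter
(exact medians, edge replication) removes speckle outliers and the
1-px-wide alignment lines without displacing edges; the frame is
resampled bilinearly onto a 200 x 630 polar grid. The grid is part of
the method's operating point: the morphological element sizes below are
calibrated in these units. Row `n_r` maps to radius `(side - 1)/2`
pixels — the largest circle fully inside the pixel grid — so one polar
row is almost exactly one Cartesian pixel at the default 400-px frame.

### Stage 2 — feature extraction

A one-level *undecimated* Haar wavelet packet frame decomposes the polar
image into four planes aligned pixel-for-pixel with the input (the
à-trous form is used precisely so that coefficients keep the image
geometry; decimated transforms would not overlay on the polar grid).
The low-pass is normalized as a pair *average*, so the approximation
plane `cA1` preserves the intensity scale and Otsu statistics on it have
the same meaning as on the image. `cA1` — a local 2x2 average — carries
the tissue evidence; the detail planes are exposed for inspection but
unused by the pipeline.

Binarization is per A-line: each polar column gets its own 256-bin Otsu
threshold. The motivating failure of a global threshold is the angular
contrast gradient of an off-center catheter: far-wall A-lines may be an
order of magnitude dimmer than near-wall ones, and a single histogram
cut discards them wholesale, while each column's own histogram remains
bimodal at any gain. Two policy details are pinned for reproducibility:

* within-bin class statistics are accumulated from the actual sample
  values, and the returned threshold is the midpoint between the two
  classes' extreme values, so the binarization reproduces the selected
  histogram partition exactly (ties break toward the lowest cut);
* a column whose intensity range is below `1e-6` of the unit scale is
  *degenerate* — it carries no contrast at all. Such columns are
  binarized as all-foreground: a shadowed A-line must not cut the
  tissue band in two, and the resulting full column registers as an
  abrupt drop of `h(theta)` that the gap machinery repairs. Only when
  *every* column is degenerate (a blank frame) does the stage return an
  empty mask, which the reconstruction reports as "no tissue detected".

### Stage 3 — binary morphological reconstruction

Polar reconstruction composes four operations with disk structuring
elements (discrete Euclidean disks; a pixel belongs iff its center lies
within the radius):

1. opening, diameter 3 px — deletes speckle-sized clutter and detaches
   noise connected to the band;
2. upward filling — column-wise flood to the bottom;
3. area selection — only the largest 8-connected component survives,
   with the angular axis circular (the seam between the last and first
   column is a true adjacency);
4. closing, adaptive diameter `D = r_max` — smooths boundary
   irregularities at the scale the catheter geometry sets, without
   bridging true branch gaps (which are wider than `D`).

Two guarantees are enforced around step 4: the bottom edge is padded
with foreground during the closing so erosion cannot detach the object
from the maximum-radius edge, and a final upward fill restores
column-solidity (a closing of a column-solid object can leave overhangs
at its margin). The result is always a single bottom-attached solid
region whose complement — the lumen — is attached to the top.

A further rule extends the degenerate-column policy into this stage: an
A-line with *no* foreground left after the opening is treated like a
no-contrast shadow column and set fully foreground before filling.
Without it, a single sector-edge A-line (partial shadow, a few sparse
pixels that die in the opening) severs the band, and area selection then
discards an entire healthy arc.

**Gap detection and repair.** Side branches cast angular shadow sectors
with no tissue return; intraluminal artifacts can likewise flood
A-lines. Both appear as abrupt excursions of `h(theta)`. On the circular
first difference `d[j] = h[j+1] - h[j]`, columns with `|d| > T`,
`T = k SD(d)` with `k = 5` by default, mark gap shoulders. The pairing
of shoulders is genuinely ambiguous when a shoulder is smeared over
several columns (each below threshold): this package classifies every
crossing as *entry* or *exit* according to which side of the jump lies
farther from the circle's median height, opens a gap at an entry,
closes it at the next exit, and ignores stray exits. The standard
deviation is taken over the full derivative signal, gap columns
included, matching the `5 SD` rule as stated. Detected gap columns, plus
a 2-column guard band (the closing rounds gap shoulders), are deleted
and re-interpolated with a shape-preserving piecewise cubic Hermite
scheme (`pracma::pchip`) on the circularly unwrapped axis; interpolated
values are rounded and clipped to `[0, n_r - 1]`.

**Cartesian reconstruction.** The negated polar object is mapped back to
the Cartesian grid (bilinear on `(r, theta)`, circular in `theta`,
mask threshold 0.5) and polished by one opening with adaptive diameter
`R_min`, the minimum lumen radius in pixels, floored at 3 px so the
element never degenerates when the lumen grazes the catheter. The
component containing (or nearest to) the center is kept. The contour is
the 0.5-level marching-squares polyline of the mask; the indicator field
is pre-smoothed with a 3x3 box filter so the level set lands on the true
boundary rather than the pixel staircase (on a binary field the
staircase inflates a disk's perimeter by about 6%; with smoothing the
error is well under 5%).

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `r_max_px` | 20 | Cartesian px | catheter-ring blanking radius; also the polar closing diameter `D` |
| `median_window` | 5 | px | despeckling window |
| `n_r`, `n_theta` | 200, 630 | samples | polar grid; fixed operating point of the morphology |
| `se_small_diam_px` | 3 | polar px | speckle-removal opening diameter |
| `gap_k` | 5 | — | derivative threshold multiplier `T = k SD(d)` |
| `fov_mm` | 6 | mm | physical field of view; sets mm-per-pixel for the metrics |
| `gap_correction` | TRUE | — | toggle for the shadow-gap repair |

Only `r_max_px` normally needs adjusting, to the catheter ring of the
acquiring system. The pipeline is fully deterministic: no step draws
random numbers.

## The accuracy panel

Area fractions are normalized by the gold area, so `TP + FN = 100` holds
by construction (`FN` is computed as `100 - TP`, which also makes the
identity exact in floating point). Maximum deviations are exact
Euclidean distances between pixel *sets* (falsely segmented pixels to
the gold set, and missed gold pixels to the segmentation), scaled by
mm-per-pixel; for solid masks this equals the contour-to-contour
deviation and avoids a contour-discretization convention. Jaccard (OR)
and Dice (OD) are linked by `OD = 200 OR / (100 + OR)`, which the test
suite verifies as an identity.

## What the phantom generator emulates — and what it does not

`generate_phantom()` composes, on a 400-px / 6-mm frame: a dark lumen
whose boundary is `rho(theta) = R0 (1 + e cos(theta - phi) +
a sin(f theta + psi))`; a tissue ring with exponential depth attenuation
and multiplicative unit-mean gamma speckle (`speckle_contrast` is its
standard deviation — any unit-mean multiplicative model suffices to
exercise the median stage, and gamma is the standard speckle family); an
angular gain factor falling to `gain_min` opposite the gain angle
(emulating catheter-offset contrast loss); a catheter-ring annulus and a
thin full-width alignment line; branch-shadow sectors in which the
tissue return beyond the lumen border is nulled while the boundary
A-lines keep no contrast (the failure mode gap correction exists for);
and intraluminal blobs. Blobs are placed in the mid-to-outer lumen
(0.45–0.8 of the local boundary radius) and clear of the catheter body —
thrombus is wall-adherent and nothing can occupy the catheter's own
footprint; bright smooth masses hugging the catheter would be both
unphysical and would corrupt the majority of A-lines at once.

The suites fix the study conditions: *easy* draws moderate speckle
(contrast 0.4), mild eccentricity and perturbation, a gain floor of
0.6–1.0, and no branches or blobs; *hard* draws speckle 0.5, a gain
floor of 0.2–0.3, one or two branch sectors of 15–40 degrees, stronger
boundary perturbation, and 2–5 blobs. Lumen radii of 0.9–1.5 mm, wall
thickness 0.6–1.0 mm and attenuation 2–4 /mm are typical of coronary
TD-OCT. Twenty frames per suite keep the full end-to-end check inside a
couple of minutes on one CPU while averaging over the parameter draws.

The phantom is *not* a wave-optics simulation: speckle is uncorrelated
between pixels (real OCT speckle has a spatial correlation set by the
point-spread function), blood appears as discrete blobs rather than
continuous backscatter texture, there are no stent struts or guide-wire
shadows, and tissue is homogeneous (no plaque layering). Passing the
phantom suites therefore demonstrates the pipeline's geometric and
morphological correctness under the modeled artifact families, not
clinical-grade accuracy on real pullbacks.

## Numerical choices and degenerate inputs

* Angular origin east, counter-clockwise; any fixed convention works as
  long as the polar and Cartesian transforms share it — both read the
  geometry recorded on the polar object.
* Bilinear interpolation in both transform directions (the method's
  source material fixes only the grid size); mask transforms threshold
  the interpolated field at 0.5.
* Otsu histograms use 256 bins over each column's own min–max range;
  bin count and tie policy are package choices, stated above.
* `detect_gaps` returns no gaps when the derivative is constant
  (`SD = 0`); `correct_gaps` refuses to run with fewer than 4 surviving
  support columns.
* An all-background feature mask raises "no tissue detected"; a
  full-foreground polar object (no lumen) raises "lumen not found".
  Errors from inside the pipeline are re-signalled with the stage name.
* `R_min` is floored at 3 px; `D` is rounded to the nearest integer.

## Problem sizes used by the checks

The test suite and the acceptance script run the full pipeline on 20
easy and 20 hard phantoms at 400 px / 6 mm, verify the Otsu
implementation against exhaustive search on 500 small histograms, and
round-trip disks of radius 30–150 px through the 200 x 630 polar grid.

## Known limitations

* The catheter center is assumed at the frame center (display-format
  convention); an off-center catheter is modeled only through the
  angular gain gradient, not through a shifted ring.
* `h(theta)` is single-valued, so extreme non-convex lumina (boundary
  folding back over itself radially) cannot be represented.
* Gap repair interpolates blindly across detected runs; a branch ostium
  wider than roughly a quadrant leaves the interpolation weakly
  constrained.
* The method targets TD-OCT texture; FD-OCT frames have different
  speckle and blood appearance and would need the feature-extraction
  stage revisited.
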