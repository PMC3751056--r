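# octlumen

Fully automatic lumen segmentation for intravascular optical coherence
tomography (IVOCT) cross-section images, with the standard segmentation
accuracy panel and a synthetic phantom generator for validation.

## The problem

IVOCT catheters image coronary arteries from the inside: each frame is a
6 mm x 6 mm cross-section with a dark blood-filled lumen, a bright vessel
wall, and hardware artifacts (a catheter reflection ring and thin
alignment-mark lines). Quantitative measures — lumen area, diameter,
stenosis — require delineating the lumen on hundreds of frames per
pullback, which makes manual and even seed-initialized segmentation
impractical. `octlumen` segments each frame with no interaction and no
training stage, using only light image-processing operations, and is
aimed at researchers processing display-format time-domain OCT frames.

## Method

The pipeline has three stages:

1. **Preprocessing.** Pixels within the known catheter-ring maximum
   radius `r_max` are blanked; a 5x5 median filter fades the alignment
   marks and speckle; the frame is resampled to polar coordinates
   `I(r, theta)` on a 200 x 630 grid (~0.57 deg per A-line), where the
   circular vessel becomes a horizontal band.
2. **Feature extraction.** One level of an undecimated Haar (db1) wavelet
   packet frame yields the approximation plane `cA1`, which concentrates
   tissue evidence. Each polar column (A-line) is binarized with its own
   Otsu threshold — per-column histograms stay bimodal even where an
   off-center catheter has destroyed absolute contrast, which a single
   global threshold cannot survive.
3. **Binary morphological reconstruction.** In the polar domain: opening
   with a 3 px disk (speckle removal), upward filling (everything behind
   the first tissue return is tissue-equivalent), largest-component
   selection on the circular grid, and closing with an adaptive disk of
   diameter `D = r_max`. Side-branch shadows leave angular runs with no
   tissue return; they are found on the height signal `h(theta)` — the
   per-A-line boundary radius — as derivative excursions beyond
   `5 SD`, and repaired by piecewise cubic Hermite interpolation. The
   negated object is mapped back to Cartesian space and polished by one
   last opening with adaptive diameter `R_min` (the minimum lumen
   radius); the lumen contour is extracted with sub-pixel marching
   squares.

Accuracy against a gold-standard mask `G` for a segmentation `S` is
reported as the seven-value panel: TP/FP/FN area fractions
(`TP = 100|S∩G|/|G|`, `FP = 100|S\G|/|G|`, `FN = 100 - TP`), maximum
false-positive/false-negative boundary deviations in mm (exact Euclidean
set-to-set distances), overlap ratio (Jaccard) and overlap Dice.

## Worked example

```r
library(octlumen)

# a synthetic frame with speckle, an eccentric lumen and a branch shadow
ph <- generate_phantom(phantom_params(
  speckle_contrast = 0.3, eccentricity = 0.08,
  branch_sectors = list(c(120, 30)), seed = 42))

res <- segment_image(ph$image, pipeline_config(r_max_px = 20), gold = ph$gold)
print(res)
#> IVOCT lumen segmentation
#>   lumen area (px): 19536
#>   contour vertices: 639
#>   gaps detected: 1 (corrected)
#>   metrics:
#>   tp_pct fp_pct fn_pct max_fp_mm max_fn_mm or_pct od_pct
#> 1 96.905      0  3.095         0     0.085 96.905 98.428
```

The branch shadow (30 degrees wide, starting at 120 degrees) is detected
as one gap in the boundary height signal and interpolated across; the
recovered lumen overlaps the ground truth with Dice 98.4%, with no
false-positive area and a largest inward boundary excursion of 0.085 mm
on the 6 mm field of view. `plot_segmentation(ph$image, res,
ph$gold)` overlays the extracted contour (green) and the gold outline
(blue) on the frame.

A shell front end with the same functionality is installed at
`inst/scripts/ivoct-lumen.R` (`segment`, `evaluate`, `phantom`
subcommands).

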