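---
title: "Measuring leaf angles from time-lapse plant images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring leaf angles from time-lapse plant images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafangler)
```

## The trait and the measurement model

Leaf angle — the angle the leaf blade makes with a vertical line ascending
from the leaf/stem junction — is a canopy-architecture trait of maize and
sorghum: erect (small-angle) leaves intercept light more efficiently at high
planting density, and a progressive *increase* in leaf angle over hours is
the visible signature of wilting under water deficit. `leafangler` extracts
this angle, per leaf and per frame, from side-view time-lapse images of a
single plant photographed against a contrasting background with an
approximately vertical stalk, and exports the trajectories as CSV.

The measurement is deliberately local and supervised: the user declares,
once per series, the stalk anchor (bottom center of the stalk) and one
rectangular region of interest (ROI) per leaf, placed close to the
leaf–stalk junction but not touching the stalk. Because camera and pot are
static, the ROIs propagate unchanged to every frame. Inside an ROI the leaf
is the dominant connected component of the segmented plant mask, and its
angle is read off the orientation of the moment-matched ellipse:

* central second moments of the component's pixel set, with a $+1/12$
  per-axis correction for the unit pixel area:
  $\mu_{20}' = \operatorname{var}(x) + \tfrac{1}{12}$,
  $\mu_{02}' = \operatorname{var}(y) + \tfrac{1}{12}$,
  $\mu_{11}' = \operatorname{cov}(x, y)$, with $y$ pointing up;
* orientation $\theta = \tfrac{1}{2}\operatorname{atan2}\!\big(2\mu_{11}',\,
  \mu_{20}' - \mu_{02}'\big) \in (-90^\circ, 90^\circ]$ from horizontal;
* leaf angle from vertical $= 90^\circ - |\theta| \in [0^\circ, 90^\circ]$,
  so an erect blade scores 0 and a horizontal one 90, identically for left-
  and right-side leaves.

Using the full component area, rather than a one-pixel skeleton, makes the
orientation estimate an average over every blade pixel in the ROI and hence
robust to boundary quantisation; a skeleton-based variant
(`use_skeleton = TRUE`) is retained for comparison.

## The processing pipeline

Each frame passes through:

1. **Channel extraction** (`to_gray`). Default: the blue channel, where
   chlorophyll-rich tissue is darkest against typical backgrounds;
   red/green/luminance are available for other acquisition regimes.
2. **Unsharp sharpening** (`sharpen`):
   `clip(g + amount * (g - blur(g, radius)), 0, 1)` with a separable
   Gaussian blur and replicated borders. Defaults `radius = 1`,
   `amount = 0.8` are the customary unsharp-mask settings; sharpening
   steepens the plant/background transition before thresholding.
3. **Complement** (`complement`): `1 - g`, making the plant the bright,
   active object.
4. **Thresholding** (`binarize`, strictly `> level`). `level = "otsu"`
   (default) maximises between-class variance on a 256-bin histogram of the
   complemented image. A numeric `level` overrides it *on the same
   plant-bright scale*, replacing the interactive threshold slider of a GUI
   workflow with a reproducible config entry. `invert = FALSE` returns the
   exact complement of the plant mask.
5. **Mask cleanup** (`clean_mask`): thicken thin structures, bridge 1-px
   breaks, 3×3 closing, and removal of components below `min_blob_area`.
6. **Optional skeletonization + spur pruning**, then per-ROI measurement.

A frame whose segmentation fails (for example, a plant-free image with a
degenerate one-bin histogram) produces missing angles for all its leaves
plus a warning — never an abort — and occluded or empty ROIs yield missing
values. The CSV always contains exactly `n_frames × n_rois` rows, with
missing angles printed as the literal `NaN`.

## Numerical choices

Several small conventions make the pipeline bit-for-bit reproducible:

* **Otsu on bin boundaries.** Intensities are binned as
  `round(g * 255)`; ties in the between-class variance break to the lowest
  bin; the returned level is the *upper boundary* `(k + 0.5)/255` of the
  maximising bin. Returning a boundary rather than a bin center matters:
  the background mode's exact intensity then cannot straddle the strict
  `>` comparison when later filtering introduces ripples of order
  `1e-8`.
* **8-connectivity everywhere** (edges or corners touching), in labeling,
  despeckling and skeleton analysis, with component labels assigned in
  raster-scan first-encounter order.
* **Thickening to a fixed point.** A naive dilation grows masks without
  bound, so repeated cleanup would never stabilise. `clean_mask` instead
  dilates only the *thin* structures — pixels removed by a 3×3 opening —
  which fattens sub-3-px lines once and then changes nothing, making
  cleanup idempotent in practice.
* **Bridging via a 256-entry neighborhood table.** A background pixel is
  set only when its foreground neighbors are *not connected within the
  3×3 neighborhood* (consecutive ring cells touch, as do orthogonal pairs
  across a missing diagonal). Pairwise "two neighbors present" tests
  would erroneously fill every straight edge. One pass only: repeated
  bridging could close real gaps between distinct leaves.
* **Homotopic thinning.** Skeletonization deletes border pixels
  sequentially, in four directional subpasses per round (north, south,
  east, west), only when the pixel is topologically simple (Yokoi
  connectivity number 1) and not an endpoint. Directional subpasses erode
  symmetrically, so 2-px-wide stubs thin to a line instead of being eaten
  end-first; simplicity guarantees the 8-connected component count never
  changes.
* **Degenerate regions.** An isotropic pixel set (a lone pixel, a disk)
  has no defined orientation: the record is missing, with a warning,
  rather than an arbitrary 0°.
* **Angles clamp to [0, 90].** Unsigned axis orientation cannot
  distinguish a blade drooping past horizontal from its mirror image; the
  convention documents that limitation rather than guessing a sign.

## The synthetic generator

`synthetic_scene()` + `wilting_schedule()` + `render_series()` draw a
vertical stalk and straight-to-mildly-curved leaves (dark green,
`plant_rgb = c(45, 85, 40)`) on a light gray background
(`c(205, 205, 205)`), so the blue channel separates the classes exactly as
in the acquisition regime the blue-channel default presumes. Leaves
auto-place bottom-up with alternating sides, mimicking the planar
phyllotaxy that lets a single side view see every blade. The schedule
models wilting as a per-leaf linear drift in angle plus Gaussian
frame-to-frame jitter (wind), clamped to [5°, 88°]; occlusions remove a
leaf's pixels entirely before noise, emulating a foreign object. Additive
Gaussian intensity noise (default `noise_sd = 5` on the 0–255 scale,
moderate sensor noise) is quantised to integers as an 8-bit sensor would
record, and all randomness flows from one seed, so renders are
bit-identical.

Ground truth per (frame, leaf) is the chord angle from the junction to the
blade tip — identical to the base angle for straight leaves, and within
~1.5° of it at the maximal curvature the generator allows (the blade
direction turns by `30 × curvature` degrees base-to-tip, bounded at
`curvature = 0.3`).

`default_rois()` places each leaf's rectangle beside its junction, offset
from the stalk edge by `margin` (default 3 px) and sized to cover the
blade's reach over the whole 5–88° angle range. The window extends along
the full blade length rather than only its proximal third: at steep
angles (≲10°) the proximal third lies almost entirely inside the stalk
margin band, and a third-sized box would contain too few leaf pixels to
measure. The wider window keeps steep leaves measurable; for straight
blades it changes nothing (every sub-segment has the same orientation),
and for curved blades the chord ground truth matches the wider measured
span.

What the generator does *not* emulate — and what passing tests therefore
do not establish — includes: leaves crossing in front of the stalk or each
other, plant rotation in the pot, non-vertical or bowing stalks, specular
soil/pot reflections, illumination drift across a day, and the
out-of-plane leaf torsion of real canopies. Results on synthetic scenes
bound the *algorithmic* error of the pipeline, not its field accuracy.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `seg$channel` | `"blue"` | – | darkest plant/background contrast for green tissue |
| `seg$level` | `"otsu"` | [0,1] | per-frame automatic threshold; numeric override available |
| `seg$sharpen_radius`, `seg$sharpen_amount` | 1, 0.8 | px, gain | customary unsharp-mask defaults |
| `morph$thicken_iters` | 1 | passes | fatten sub-3-px structures once |
| `morph$min_blob_area` | 50 | px | speckle floor, calibrated to multi-megapixel frames; scale down for small fixtures |
| `morph$prune_spur_len` | 10 | px | spur length removed when skeletonizing |
| `min_area` | 20 | px | smallest component accepted as a leaf inside an ROI |
| `margin` (`default_rois`) | 3 | px | gap between stalk edge and ROI |

## Problem sizes used by the test-suite

The packaged checks run on 320 × 240 px scenes with three 72-px leaves:
20 seeded scenes × 5 frames per recovery arm (300 matched pairs each,
noiseless and `noise_sd = 10` with curvature up to 0.15), 200 random
images for the Otsu oracle, 100 point clouds for the orientation oracle,
100 random masks for skeleton connectivity, an 81-step rotation sweep,
and 50 seeded 60-frame replicates for wilting discrimination. These sizes
keep a full run in the minutes range on one CPU while leaving every
statistic estimable.

## Known limitations

* Angles past horizontal fold back into [0, 90]; genuinely drooping
  blades are indistinguishable from their reflection.
* One plant per scene; ROIs are static, so a plant that rotates or sways
  out of its boxes will silently measure the wrong pixels (place wider
  ROIs or re-declare them per segment of the series).
* The stalk is assumed vertical; no tilt correction is applied.
* Between-genotype comparisons of absolute angles inherit every placement
  choice made per plant and should be treated with caution; the tool's
  strength is *within-leaf trajectories over time*.
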