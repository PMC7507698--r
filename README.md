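# leafangler

Leaf angle — the angle between a leaf blade and a vertical line rising
from the leaf/stem junction — is a key canopy-architecture trait in maize
and sorghum: erect leaves capture light efficiently at high planting
density, and a *progressive increase* in a leaf's angle across a
time-lapse series is the visible signature of wilting under drought.
`leafangler` measures this angle per leaf and per frame from side-view
still images of a single plant, tracks the trajectories across the
series, and exports them as CSV. It is aimed at plant phenotyping
workflows where a camera photographs one potted plant against a
contrasting background at regular intervals.

## Method

Each frame is segmented into plant and background — blue-channel
extraction, unsharp sharpening, complement, and Otsu-initialised
thresholding (strict `>`, 256-bin histogram, deterministic tie-breaks) —
then the binary mask is cleaned: thin structures thickened, 1-px breaks
bridged, a 3×3 closing, and speckle components below an area floor
removed. The user declares, once per series, the stalk anchor and one
rectangular ROI per leaf next to its junction (not touching the stalk);
ROIs propagate unchanged to all frames. Inside an ROI, the largest
8-connected component is the leaf, and its angle comes from the
moment-matched ellipse of the pixel region:

    mu20' = var(x) + 1/12      mu02' = var(y) + 1/12      mu11' = cov(x, y)
    orientation = 1/2 * atan2(2 mu11', mu20' - mu02')   in (-90, 90]
    leaf angle  = 90 - |orientation|                    in [0, 90]

with y pointing up: 0° = fully erect, 90° = horizontal. Occluded or empty
ROIs produce missing values written as the literal `NaN`; the CSV always
holds exactly `n_frames × n_leaves` rows. A synthetic plant generator
(vertical stalk, straight or curved leaves at known angles, wilting
drift, jitter, sensor noise, occlusions) provides ground truth for every
stage, and `validate_against_truth()` reports Pearson *r* and mean
absolute error against any truth table.

## Worked example

Render a 30-frame synthetic plant whose third leaf wilts (+0.4°/frame),
then measure it:

```r
library(leafangler)

scene    <- synthetic_scene(base_angles = c(25, 45, 65), noise_sd = 5, seed = 42)
schedule <- wilting_schedule(30, c(25, 45, 65),
                             drift_per_frame = c(0, 0, 0.4),
                             jitter_sd = 0.5, seed = 42)
rs     <- render_series(scene, schedule, "demo_plant")
layout <- default_rois(scene)

series  <- load_series("demo_plant", "frame_*.png")
records <- measure_series(series, layout$anchor, layout$rois)
records
#> # A tibble: 90 × 4
#>   frame_index filename       leaf_id angle_deg
#>         <int> <chr>            <int>     <dbl>
#> 1           0 frame_0001.png       1      25.2
#> 2           0 frame_0001.png       2      44.9
#> 3           0 frame_0001.png       3      64.7
#> # ...

glance(records)
#> # A tibble: 3 × 7
#>   leaf_id n_frames n_missing mean_angle_deg min_angle_deg max_angle_deg ...
#> 1       1       30         0           24.5          23.1          25.6
#> 2       2       30         0           44.8          43.3          45.7
#> 3       3       30         0           70.8          64.7          77.0

validate_against_truth(records, rs$truth)
#> <angle_validation> n = 90 pairs, Pearson r = 1.000, MAE = 0.27 deg
```

Leaf 3's trajectory climbs ~12° across the series while leaves 1–2 stay
flat — exactly the drift the schedule injected — and the per-frame
measurements track the known ground truth to a fraction of a degree.
`autoplot(records)` draws the per-leaf trajectories;
`write_angles_csv(records, "angles.csv")` exports them.

Real series work the same way: point `load_series()` at the image
directory and declare the anchor/ROIs in a YAML config (see
`run_config()` / `read_run_config()`), or use the bundled CLI:

```sh
inst/exec/lax synth --out demo --n-frames 30 --seed 1 --drift 0.4
inst/exec/lax run --config demo/config.yaml
inst/exec/lax validate --records demo/angles.csv --truth demo/truth.csv
```

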