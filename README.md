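# sproutlab

Quantitative image and track analysis for sprouting-angiogenesis
assays, for labs running endothelial-cell (EC) spheroid sprouting,
3D traction force microscopy (TFM) around sprouts, tip-cell morphology
scoring, and gap-closure migration experiments. The package implements
the measurement side of these assays — segmentation-based kinetics,
displacement-field reduction, shape and intensity readouts, and
trajectory decomposition — together with seeded synthetic-data
generators that carry programmed ground truth, so every stage is
testable without raw microscopy data.

## What it computes

**Spheroid sprouting kinetics.** Brightfield frames are segmented by a
local standard-deviation filter (texture inside the spheroid, smooth
background outside), Otsu threshold, closing, hole filling and
largest-component selection. Per frame, relative to the first
timepoint:

- tip-cell distance `d_TC(t) = max over mask_t of EDT(outline_0)`
  (interior of the t = 0 body clipped to zero), in µm — how far the
  leading tip cell has migrated beyond the original spheroid surface;
- invasion area `A(t) = |mask_t| − |mask_0|`, in µm².

**Sprout mechanics.** Given a 3D sprout mask and a displacement field
u sampled at fiducial beads (µm), the pipeline thins the mask to a
medial curve, walks the base→tip geodesic in 1 µm stations, and reports
the signed line scan

`s(ℓ) = |ū(ℓ)| · sign(ū(ℓ) · ĝ)`

where ū(ℓ) is the mean displacement vector of near-surface points
(0–5 µm shell) assigned to station ℓ and ĝ the base→tip principal axis
of the path; negative values mean matrix pulled toward the sprout
origin. Also: mean and maximum |u| over the 0–5 µm shell, and
length-normalized (λ ∈ [0, 1]) averaging of profiles across sprouts.

**Cell shape and intensity.** Solidity = mask area / convex-hull area
(1 for protrusion-free elliptical cells, lower with filopodia);
periphery-inward intensity profiles averaged over cells;
membrane/whole-cell intensity ratio as a percentage; filopodia counts
per 100 µm free edge.

**Migration components.** Tracks longer than 15 frames (strict) are
decomposed into directed velocity `v_y` (polynomial fit of y vs frame,
px/frame) and diffusivity `D_xy = (var(Δx_res) + var(Δy_res))/4`
(px²/frame, drift-removed, consistent with MSD = 4Dt), plus
time-averaged MSD curves and Welch two-sample comparisons.

## Worked example

```r
library(sproutlab)

# a synthetic spheroid time-lapse with programmed growth (2 px/frame)
scene <- make_spheroid_timelapse(n_frames = 4, seed = 7)
ks <- kinetics_curves(scene$stack)
ks$per_replicate[[1]]
#>   frame time_h tc_distance_um invasion_area_um2
#> 1     0      0       0.000000            0.0000
#> 2     1      6       1.838478           30.4200
#> 3     2     12       2.055480           35.0675
#> 4     3     18       3.250000           44.3625
```

The programmed truth is `0, 1.3, 2.6, 3.9` µm of tip extension
(2 px/frame at 0.65 µm/px); the measured curve tracks it to within the
segmentation's ~2–3 px accuracy, and area grows monotonically.

```r
# tip-cell morphology: protrusions lower solidity
solidity(make_spiky_mask("ellipse", c(50, 30), n_spikes = 0))
#> <solidity_result> solidity 1.0000 (area 4716 px^2, hull 4716 px^2)
solidity(make_spiky_mask("ellipse", c(50, 30), n_spikes = 10,
                         spike_length_px = 25, seed = 2))
#> <solidity_result> solidity 0.5027 (area 5188 px^2, hull 10320 px^2)

# migration decomposition on synthetic drift+diffusion tracks
ts <- make_tracks(track_params(200, 100, drift = c(0, 0.6),
                               diffusion = 0.4, seed = 3))
comp <- migration_components(filter_tracks(ts, 15))
round(c(v_y = mean(comp$v_y), D_xy = mean(comp$D_xy)), 4)
#>    v_y   D_xy
#> 0.6045 0.4042
```

The generator's truth was drift 0.6 px/frame and diffusivity
0.4 px²/frame: both recovered within about 1%.

A command-line front end (`inst/cli/sproutlab.R`) exposes the same
pipelines as subcommands (`simulate`, `kinetics`, `profile`,
`solidity`, `migration`, `ratio`), e.g.

```sh
Rscript inst/cli/sproutlab.R kinetics --input stack.tif \
    --pixel-size 0.65 --frame-interval 6 --out kinetics.csv
```

Every CSV the pipeline writes starts with a comment line carrying a
hash of the configuration that produced it.

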