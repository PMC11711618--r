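---
title: "Quantifying sprouting angiogenesis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sprouting angiogenesis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sproutlab)
```

`sproutlab` packages the measurement procedures used to quantify
endothelial-cell (EC) sprouting assays: spheroid outgrowth kinetics from
brightfield time-lapse, matrix displacement fields around 3D sprouts
from traction force microscopy (TFM), tip-cell shape, and the
drift-diffusion decomposition of cell trajectories from gap-closure
(wound-healing) assays. Every stage has a seeded synthetic generator
with programmed ground truth, so the whole pipeline can be validated
without raw microscopy data. This vignette explains each model, the
parameters that matter, and the design decisions taken where the
procedure left genuine freedom.

## Spheroid sprouting kinetics

EC spheroids embedded in fibrin sprout radially over days. In
brightfield, the cellular structure shows heterogeneous intensity
(texture) while the gel background varies smoothly. `segment_spheroid()`
exploits exactly this contrast: a local standard-deviation filter
(window `std_window_px`, default 9 px) lights up textured regions, an
Otsu threshold binarizes the response, morphological closing (disc,
radius `morph_radius_px` = 3 px) consolidates it, holes are filled, and
the largest connected component is kept so floating debris cannot win.

Two scalar summaries are computed per frame, both relative to the first
timepoint (before sprouting starts):

* **Tip-cell (TC) distance** — the Euclidean distance transform of the
  *t = 0 spheroid outline* is evaluated over the current mask and its
  maximum is reported in micrometres. Distances of pixels *inside* the
  original body are clipped to zero first. Without that clipping a
  sproutless spheroid would report its own radius, because the distance
  transform of an outline is positive on both sides; with it, the value
  is the distance the leading tip cell has migrated beyond the original
  surface, and is exactly 0 at t = 0.
* **Invasion area** — current mask area minus t = 0 mask area, in
  square micrometres. Negative values (a shrinking spheroid) are
  reported as-is.

The distance transform is an exact separable Euclidean transform
(lower-envelope-of-parabolas construction) written for this package; it
supports anisotropic sampling and treats image borders correctly, which
matters because the t = 0 outline is an interior structure.

```{r kinetics-example}
scene <- make_spheroid_timelapse(n_frames = 4, seed = 7)
kin <- kinetics_from_masks(scene$true_masks, scene$pixel_size)
kin
```

**What the generator emulates, and what it does not.** The synthetic
scene renders a disk-shaped body with rectangular sprouts growing at a
programmed rate, multiplicative speckle (grain about 2 px) inside the
mask, a smoothly varying background of matched mean intensity, and
additive Gaussian camera noise. That reproduces the *segmentation
premise* (texture inside, smoothness outside) but none of the optics:
no point-spread function, no phase-contrast halo, no focus drift, no
debris, and sprouts that are straight and of constant width. Passing
the recovery tests therefore demonstrates that the measurement
operations are correct and that the segmentation works when its premise
holds; it does not certify segmentation robustness on adversarial real
data.

**Accuracy.** On generator scenes the segmentation overlaps the true
mask with Jaccard index above 0.9 (typically 0.95+). The
standard-deviation window leaves a halo of roughly half its width, so
segmented masks are uniformly slightly dilated; the halo mostly cancels
in the TC distance (outline and tip shift outward together), leaving a
net full-pipeline accuracy of about 3 px. The invasion-area
*difference*, however, inherits the halo along every sprout flank, so
area kinetics through segmentation are accurate in shape but biased in
magnitude for few-pixel-wide sprouts; the measurement operation itself
is exact given correct masks. Replicate curves are aggregated as mean
with a standard-deviation band; `normalize = TRUE` divides the mean
invasion-area curve by its maximum (the normalization constant is not
otherwise prescribed, so the curve maximum is used).

## Displacement fields around 3D sprouts

TFM reports matrix displacements at fiducial beads between a stressed
state and a relaxed state (after pharmacological relaxation of the
cytoskeleton). Downstream of the (out-of-scope) inverse computation,
the pipeline reduces a displacement field plus a binary sprout mask to:

1. **Near-surface mean** — the mean displacement magnitude over field
   points within 0–5 µm of the sprout surface (`surface_shell()`,
   `mean_shell_displacement()`). Surface distance is measured to
   boundary-voxel centres with an exact bucket-grid nearest-neighbour
   search; points whose containing voxel is inside the mask are
   excluded.
2. **Signed line scan** — the sprout mask is thinned to a medial curve,
   base and tip are selected, and the geodesic path between them (steps
   weighted by physical, possibly anisotropic voxel size) is walked in
   1 µm arc-length stations. Shell points are assigned to their nearest
   station; per station the displacement *vectors* are averaged and the
   result is reported as |mean vector| signed by its dot product with
   the growth direction. The growth direction is the first principal
   axis of the path, oriented base to tip, so negative values mean the
   matrix is pulled back towards the sprout origin — the signature of a
   contractile tip.
3. **Per-sprout maximum** — the largest displacement magnitude in the
   0–5 µm shell.
4. **Length-normalized averaging** — each sprout's line scan is mapped
   onto a common 0 (base) to 1 (tip) axis (51 points), interpolating
   over missing stations, and averaged across sprouts with a
   standard-deviation band.

```{r phantom-example}
ph <- make_sprout_phantom(peak_magnitude_um = 2, n_beads = 800, seed = 1)
geom <- sprout_geometry(ph$mask, ph$voxel_size, reference_point = ph$true_base)
prof <- signed_profile(ph$field, geom)
range(prof$signed_disp_um, na.rm = TRUE)
```

Design decisions worth knowing:

* **Sign convention.** The principal axis of a path is defined only up
  to sign; it is fixed by requiring a positive dot product with
  (tip − base). A tip-ward pull on the matrix is then positive and a
  root-ward (contractile) pull negative.
* **Thinning.** The skeleton is produced by sequential deletion of
  simple points (points whose removal preserves local foreground
  26-connectivity and background 6-connectivity), in six directional
  sub-iterations per pass ordered by distance-to-background, protecting
  curve endpoints. Symmetric peeling makes a ball collapse to its
  centre rather than leaving a one-sided spur. Side branches shorter
  than `prune_um` (default 5 µm) from their junction are removed; real
  sprout masks are mildly lumpy and grow short spurs.
* **Endpoints.** The procedure being emulated selects base and tip
  manually. The automated default takes the skeleton endpoint nearest a
  user-supplied reference point (the spheroid/carrier-bead centre) as
  the base and the endpoint at maximal *geodesic* distance from it as
  the tip; manual points are accepted and snapped to the skeleton.
* **Station assignment.** Shell points map to their nearest station by
  Euclidean distance. Projection onto the path would be an alternative;
  nearest-station was chosen because it is unambiguous at the tip,
  where the path ends but the shell wraps around the cap.
* **Missing stations** are reported as `NA`, never as zero — zero
  filling would bias averaged profiles towards zero exactly where
  sprouts are sparsely sampled.
* **Averaging order.** Vectors are averaged first and the magnitude
  taken afterwards (then signed). Averaging magnitudes first would
  discard cancellation between opposing vectors; the vector-mean
  reading follows from treating the station average as an estimate of
  the local field.

The phantom generator builds a capsule (cylinder with hemispherical
caps) and a field `u(x) = -peak * exp(-d_tip(x)/decay) * g`, where
`d_tip` is the distance to the tip-cap surface: displacement magnitude
is exactly `peak` on the tip cap and decays into the gel, pulling
towards the base. The measured setting it emulates is a contractile tip
with displacements peaking around the sprout tip; it does not model
fibre mechanics, non-affine gel deformation, or bead localization
noise. Default bead count (2000 in a roughly 64 × 34 × 34 µm volume)
corresponds to a mean bead spacing of ~3 µm, typical of high-density
fiducial seeding. `match_beads()` provides mutual-nearest-neighbour
pairing of stressed/relaxed bead sets as plumbing; mutual-NN mispairs
beads whose displacement exceeds half the local bead spacing, which is
why matching quality, not just bead count, bounds recoverable
displacement in practice.

## Tip-cell shape and intensity readouts

* **Solidity** (`solidity()`) — mask area over convex-hull area. The
  hull is rasterized (pixel count of the filled hull of the mask's
  pixel centres), so any convex digital shape scores exactly 1 and the
  value never exceeds 1. A protrusion-free, "bullet-like" tip cell
  scores near 1; filopodia lower it. Grayscale ROIs are contrast
  stretched (2–98 percentiles), Otsu binarized and smoothed by opening
  and closing with a radius-2 disc; the smoothing method and
  percentiles are not prescribed anywhere, so they are exposed as
  arguments.
* **Edge profiles** (`edge_profile()`) — channel intensities sampled
  bilinearly at 1 px steps along user lines from the cell periphery
  inward, min-max normalized per cell, averaged across cells with an
  SD band. Cells are averaged over the distance range covered by all
  lines.
* **Membrane/cytosol ratio** (`membrane_cytosol_ratio()`) — total
  intensity in the membrane ROI over total intensity in the whole
  cell, as a percentage; by construction in [0, 100].
* **Filopodia density** (`filopodia_density()`) — a count normalized
  per 100 µm of free edge. Detection itself is delegated to external
  tooling; only the normalization lives here.

## Migration component analysis

Trajectories from a gap-closure assay are decomposed into a directed
and a random component. Tracks with 15 frames or fewer are discarded
(strictly more than 15 are required — a 15-frame track is excluded, a
16-frame track kept). Per track:

* `velocity_y()` fits y against frame with a least-squares polynomial
  (degree 1 by default, the minimal reading of "polynomial curve
  fitting") and reports the mean derivative over the track's span — for
  degree 1, the slope, in px/frame.
* `diffusivity_xy()` removes the fitted polynomial drift from x and y
  and estimates `D = (var(dx) + var(dy))/4` from frame-to-frame
  residual displacements, in px²/frame. "Standard deviation of the
  positions" is ambiguous between positions and displacements and does
  not specify a per-frame normalization; the displacement reading was
  chosen because it carries the printed units, is invariant to constant
  drift by construction, and is consistent with a 2D random walk whose
  ensemble mean-square displacement is `MSD = 4 D t` — which is exactly
  how the track generator is built (`x` and `y` steps of variance
  `2 D` per frame plus drift). The literal position-variance reading is
  available behind `method = "position"` for comparison. Frame gaps are
  skipped, never interpolated.
* `msd()` computes the time-averaged mean-square displacement and can
  fit `slope/4` over the first lags, the convention for single-particle
  tracking of membrane receptors.
* `compare_groups()` is a two-sided Welch t-test
  (Welch–Satterthwaite degrees of freedom). Two constant, equal groups
  return p = 1 by convention rather than erroring.

```{r migration-example}
ts <- make_tracks(track_params(200, 100, drift = c(0, 0.6), diffusion = 0.4,
                               seed = 3))
comp <- migration_components(filter_tracks(ts, 15))
c(v_y = mean(comp$v_y), D_xy = mean(comp$D_xy))
```

On a 3 × 3 grid of drift (0–1 px/frame) by diffusion (0.1–2 px²/frame),
500 tracks of 200 frames recover both parameters within 5% of truth;
those problem sizes were chosen because the standard error of the
ensemble means is then comfortably below the 5% band while a full grid
still runs in seconds.

## Numerical choices and degenerate inputs

* All public geometry is in micrometres (µm, µm²); track analytics stay
  in pixels and frames, matching how such data are reported.
  Coordinates are 0-based with the pixel/voxel-centre convention.
* Ties in Otsu thresholds, hull vertices and nearest stations resolve
  deterministically (first index); fixed seeds make every generator
  bit-reproducible, and each generator seeds its own stream and
  restores the caller's RNG state.
* Empty masks, flat images, empty shells, cyclic skeletons,
  rank-deficient fits and zero-variance groups raise errors (or, where
  a convention exists, return it) rather than propagating NaN.
* The exact nearest-neighbour search used for shells and bead matching
  expands bucket rings until provably no closer point exists; with a
  search radius it stops early for far queries, and membership within
  the radius remains exact.

## Known limitations

* The segmentation halo bias (about half the std-filter window) is not
  corrected; TC distance benefits from cancellation but absolute
  invasion areas through segmentation are biased for thin sprouts.
* Skeleton-based lengths are quantized to voxel steps and the medial
  curve ends about one radius short of the true tip apex; profiles are
  indexed by path arc length, not anatomical tip position.
* `edge_profile()` truncates to the shortest common line length rather
  than renormalizing per-cell distances.
* The generators emulate the geometric and statistical premises of each
  measurement, not microscope physics; conclusions about robustness to
  optical artefacts cannot be drawn from them.
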