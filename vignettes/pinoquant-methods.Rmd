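---
title: "Quantifying macropinosome membranes, tubules and cargo: methods"
author: "pinoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying macropinosome membranes, tubules and cargo: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pinoquant)
```

# Scope and data model

`pinoquant` quantifies multi-channel fluorescence imaging of
macropinocytic cells: 2-D time-lapses (frames every few seconds) and
z-stacks, stored as multi-page TIFF with a JSON sidecar carrying physical
calibration. The working container is the `image_stack`: a 4-D array
indexed `[plane, channel, row, col]` with nm/px, s/frame or nm/z-step
attached. All coordinates in the package are 0-based `(row, col)` with
pixel centers at integer positions; intensities are converted to doubles
on load and saturation is not modeled, because every measurement below is
a mean or sum statistic.

The default calibration — 80 nm/px, 3 s frames, 250 nm z-steps — matches
spinning-disk live imaging of RPE-1-sized cells; all defaults live in
`analysis_config()` and every one of them is a plain argument.

# Measurement models

## Structure segmentation and intensity

Marker-positive organelles are segmented per plane by thresholding (Otsu
on the plane's own histogram by default; an absolute threshold for
calibrated synthetic data), labeling 8-connected components and removing
components under `min_structure_area_px = 5` px. Five pixels at 80 nm/px
is about one diffraction-limited spot (240 nm), so smaller components are
indistinguishable from noise. Mean and sum intensities are measured per
channel over each label; no background is subtracted at this stage, so
adding a constant c to a channel raises every structure mean by exactly c.
Datasets are made comparable across staining and acquisition sessions by
dividing each value by its experiment's mean (`normalize_by_experiment`),
which fixes every experiment's normalized mean at 1.

## The circumferential CV tubulation statistic

Tubules nucleate at bright membrane spots, so non-uniformity of a
membrane marker along the circumference of a macropinosome is a proxy for
tubulation. The statistic is computed exactly as a manual line
measurement would be: a closed contour around the limiting membrane, a
3-px-wide band average at ~1 px arc spacing along it
(`contour_profile`), and the coefficient of variation

$$\mathrm{CV} = \frac{s}{\bar{x}}$$

of those samples. The SD convention is the sample SD (n−1 denominator);
the population convention is a one-line config switch
(`cv_sd_denominator`), and the CV is invariant under multiplicative gain
either way, so the choice matters only in the second decimal at typical
sample counts. Only macropinosomes above
`min_macropinosome_diameter_um = 1` µm qualify — smaller vesicles have
too few independent samples along the circumference.

Two contour-placement details matter. `extract_contour` traces the outer
iso-level boundary of the segmented structure and reports the
area-equivalent diameter `2·sqrt(area/π)·pixel_size_nm`. Because a
thresholded boundary sits on the outer intensity slope rather than on the
membrane itself, `snap_contour_to_ridge` moves each contour point along
its local normal to the intensity maximum before profiling — the
automated equivalent of drawing the line on the membrane. CV values are
computed on raw intensities: the statistic is gain-invariant, so
normalization would only matter through additive offsets, which the
microscope's background subtraction handles upstream.

## Tubule detection and positivity calls

Tubules are defined operationally as membrane deformations longer than
`tubule_min_length_px = 6` px at 80 nm/px. Detection separates each
vesicle mask into body and protrusions by morphological opening with a
disc scaled to the maximal inscribed radius; each 8-connected protrusion
is thinned (Zhang–Suen) to a skeleton for the intensity band, and its
length is the farthest reach of the protrusion from the body. The
thresholded tip extends past the true tip by the same intensity tail that
the body extends past the limiting membrane, so this length estimator is
accurate to about one pixel on synthetic tubules; the six-pixel cut is
strict (a 5–6 px protrusion is rejected).

A tubule is *marker-positive* when the mean signal over a
`profile_width_px = 3` band around its skeleton is at least
`positive_fold_threshold = 1.5` times the cytoplasmic background — the
boundary is inclusive, reading "at least 50% above background" as
signal ≥ 1.5 × background. Background is the mean of a
`background_square_px` square (100 px by default) placed inside the cell
and off all segmented structures; automatic placement scans raster order
and takes the first valid position, so it is deterministic. Each cell is
one biological data point: the per-cell positive fraction is reported,
and a cell with no tubules yields a missing fraction rather than zero.

## Cross-tubule profiles

Line profiles across tubules (3-px width, 1-px sampling) are aligned by
shifting each profile — without wrapping, since a tubule cross-section is
not periodic — so its reference-channel maximum (first occurrence on
ties) lands at the common centre index `floor((L−1)/2)`. The per-profile
background is the mean outside a `profile_exclusion_window_px = 15`
window centred on the peak; dividing each channel by its own background
expresses profiles as fold-change over cytoplasm, which pins the
off-window mean of every normalized profile at exactly 1. Aggregates
report the per-position mean and t-based 95% CI over non-missing samples,
with per-position n, so profiles of unequal length contribute wherever
they have data.

## Membrane recruitment traces

Recruitment of membrane proteins to a single macropinosome is measured by
a circular ROI (`membrane_roi_diameter_px = 10`) that follows a marked
point on the limiting membrane; each channel is averaged over pixels
whose centers fall inside the disc, and ROIs that leave the image yield
missing samples rather than errors. Traces are normalized to their own
mean per channel and aligned by whole-sample shifts — the acquisition
grid is 3 s, and the reference peak is placed at
`trace_align_time_s = 15` s, i.e. sample index 5 — with ties going to the
earliest peak. Whole-sample shifting preserves the sample multiset; no
interpolation is performed. For treatments that abolish the reference
peak the same pipeline runs with `align = FALSE`. With a single trace the
aggregate CI is undefined and flagged missing.

## Tracking and maturation fates

Per-frame detections are linked into tracks by greedy
mutual-nearest-neighbour assignment: closest admissible (track,
detection) pairs join first, displacement capped at
`max_displacement_nm = 1600` (two typical vesicle radii) scaled by the
bridged gap, gaps up to `max_gap = 2` frames closed. At macropinosome
densities (tens of structures per field, separations much larger than
frame-to-frame motion) this simple linker agrees with full LAP assignment
while remaining transparent; the quantities reported — diameters,
frequencies, fates — are robust to linker details at these densities.

Because limiting membranes segment as rings, detections are measured on
hole-filled structures and the radius of a hollow structure is corrected
from the filled outer radius to the ring centerline
(`r = r_fill − ring_area/(4πr)`, solved by fixed-point iteration); solid
structures keep the plain area-equivalent radius `sqrt(area/π)·nm/px`.
This keeps reported radii on the membrane rather than on the outer edge
of the thresholded band, which matters at the 400-nm exclusion boundary.

Newly formed macropinosomes are isolated by two filters: tracks with
median equivalent radius under `min_track_radius_nm = 400` and tracks
present from the first frame are excluded. Per-track diameter is twice
the median equivalent radius over the track's lifetime (the median is
insensitive to the dim birth and death frames); formation frequency is
`count/(n_cells × duration_min)`.

A track's fate is `success` when the maturation-marker mean inside the
vesicle exceeds `success_fold = 1.5` times cytoplasmic background for at
least `success_min_frames = 2` consecutive frames — single-frame blips do
not count; `failure` when the track terminates before the movie ends
without acquisition (failed macropinosomes re-fuse with the plasma
membrane and disappear); `censored` when the movie ends first. Censored
tracks are excluded from the success-rate denominator. The fold/frames
constants mirror the tubule-positivity convention and are configurable;
they are calibration choices of this package, since the original
assessments of marker acquisition were made visually.

## Fluid-phase cargo

Whole-cell dextran is measured on sum projections of z-stacks: total
in-mask intensity minus the mean of a 100×100 px background square
outside all cells times the in-mask pixel count. Negative totals are not
clamped — clamping would bias per-experiment averages upward at low
signal. Organelle-specific dextran uses the single most in-focus plane,
chosen by normalized variance (variance/mean², a standard autofocus
score; ties to the lowest index), segments the organelle marker inside
the cell mask with the same 5-px minimum, and sums dextran over all
organelle pixels. Colocalization is the plain Pearson correlation over
in-mask pixels; constant channels are an error rather than a silent NaN.

## Nested (superplot) statistics

Cells within an experiment are not independent samples of the
between-experiment variability, so summaries nest: cell values average
into one mean per experiment, and the grand mean and t-based 95% CI are
computed across the (unweighted) experiment means. With n experiments the
CI half-width is `qt(0.975, n−1)·sd/sqrt(n)`; n = 1 flags an undefined
CI. Where a figure legitimately pools per-structure values instead, the
pooled variant is a flag. Multiple comparisons use the Holm–Šidák
step-down adjustment: sort p-values ascending, set
`adj_(i) = max_(j≤i) (1 − (1 − p_(j))^(m−j+1))`, clamp at 1, restore
order. Adjusted values dominate raw ones and are monotone in the sorted
order; rejections agree with the sequential Šidák-level rule.

# The synthetic scene generator

Real raw imaging for this biology is rarely deposited, so validation
rests on `render_scene`/`render_timelapse`, which draw scenes whose every
structure is recorded in a ground-truth object: cells on a jittered grid
with cytoplasmic background, macropinosomes as annuli with Gaussian
cross-section (σ = 1.5 px) at diameters 0.4–3 µm, tubules as line
segments of the same cross-section rooted on the annulus and pointing
radially outward with jittered angles, bright nucleation spots at tubule
roots, marker-bright and marker-dim tubules in known proportion, hard-
edged punctate organelles, dextran filling vesicle and organelle lumens,
and a plasma-membrane outline channel. Time-lapses add Poisson-timed
births, Bernoulli maturation (`maturation_success_prob`), a biphasic
membrane-marker envelope peaking at configurable frames after birth,
maturation-marker onset a fixed number of frames after birth for
successful vesicles, disappearance after `failure_lifetime_frames` for
failures, and Gaussian per-frame centroid jitter (1 px default). Noise is
applied last: Poisson shot noise at a configurable photon gain plus
Gaussian read noise, clamped at zero. Every render is a pure function of
its parameters and seed (a local RNG is used and restored), so all
stochastic stages are bit-reproducible.

What the generator does *not* emulate — and therefore what passing tests
do not establish about real data: optical PSF structure beyond the
Gaussian cross-section, photobleaching, vesicle fusion/fission, crowded
fields where structures touch, camera fixed-pattern noise, and true 3-D
blur (z-planes are rendered independently). Analyses validated here are
validated for geometry and statistics, not for robustness to every
microscope artifact.

# Numerical and design choices

* **Thresholding**: the original workflow segmented with unstated manual
  settings; the package defaults to Otsu for automation with an absolute
  override for calibrated data. A constant image has no Otsu threshold
  and errors loudly.
* **Connectivity** is fixed at 8-connected; labeling is implemented
  in-package because the EBImage labeler is 4-connected.
* **Tie-breaks** are all deterministic: first occurrence for profile
  peaks, earliest for trace peaks, lowest index for focus planes,
  raster-first for background squares.
* **Contours** are oriented counter-clockwise starting at the boundary
  point nearest the image origin — CV is order-invariant, but profiles
  must be reproducible.
* **Degenerate inputs** error rather than guess: structures touching the
  image border (incomplete circumference), profiles shorter than the
  exclusion window + 2, zero-mean profiles/traces, empty experiments,
  p-values outside [0, 1].
* **Problem sizes** used in the shipped tests and acceptance script were
  chosen to exercise every path at the package's study conditions while
  keeping a full run in minutes on one core: fields of 128–320 px, movies
  of 26–100 frames, 20-seed replications for stochastic recoveries, and
  1000 replicates for CI coverage. Each is a plain argument and scales
  up unchanged.

# Known limitations

Touching organelles are not watershed-split; tubule dynamics (growth and
scission kinetics) and 3-D tubule tracing are out of scope; linking does
not resolve fusion/fission lineages; the ImageJ binary `.roi` format and
proprietary microscope formats are not read (use the CSV/JSON ROI schema);
and the maturation-fate constants, while mirroring the 1.5× positivity
convention, remain calibration choices that should be re-examined against
manually scored movies before biological use on a new marker pair.
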