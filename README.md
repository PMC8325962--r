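# pinoquant

Quantitative image analysis of macropinosome membranes, tubules and
fluid-phase cargo in multi-channel fluorescence microscopy.

Macropinosomes are large (0.4–3 µm) endocytic vesicles that either mature
into early endosomes — acquiring PtdIns3P on their limiting membrane — or
fail and re-fuse with the plasma membrane. Their membranes remodel
vigorously: thin tubules nucleate at bright protein spots on the limiting
membrane and extrude recycling cargo. `pinoquant` provides the complete
measurement chain used to quantify this biology from time-lapse and
z-stack images, together with a synthetic scene generator with exact
ground truth, so that every stage of the pipeline is testable end to end.

## What it measures

* **Structure segmentation and intensity** — marker-positive organelles of
  at least five pixels (Otsu or absolute threshold, 8-connected), with
  per-channel mean/sum intensities and per-experiment normalization
  (`segment_structures`, `measure_structures`, `normalize_by_experiment`).
* **Circumferential CV (tubulation statistic)** — a three-pixel-wide
  profile around the limiting membrane of each macropinosome > 1 µm in
  diameter; the coefficient of variation CV = s/x̄ (sample SD over mean) of
  that profile reports tubule nucleation, because nucleation spots are
  bright and local (`extract_contour`, `contour_profile`,
  `tubulation_cv`).
* **Tubule calls** — protrusions longer than six pixels (80 nm/px) are
  detected by morphological opening and skeletonized; a tubule is
  marker-positive when its band intensity is ≥ 1.5× the cytoplasmic
  background measured in a 100×100 px square (`detect_tubules`,
  `cytoplasmic_background`, `classify_tubules`).
* **Cross-tubule profiles** — line profiles aligned at the reference
  marker peak, normalized to fold-change over the background outside a
  15-px window, averaged with t-based 95% CIs
  (`align_and_normalize_profiles`).
* **Membrane recruitment traces** — ten-pixel circular ROI following the
  limiting membrane over time, normalized per trace and aligned so the
  reference peak sits at 15 s (3-s frames) (`sample_membrane_roi`,
  `normalize_trace`, `align_traces`).
* **Tracking and maturation** — per-frame detections linked by greedy
  mutual-nearest-neighbour with gap closing; tracks with median radius
  < 400 nm or present from the first frame are excluded; diameters,
  formation frequencies (events/cell/min) and success/failure/censored
  fates are reported (`detect_per_frame`, `link_tracks`,
  `filter_new_tracks`, `track_metrics`, `classify_maturation`).
* **Fluid-phase cargo** — sum projections, background-subtracted
  whole-cell dextran, per-organelle dextran on the best-focus plane, and
  masked Pearson colocalization (`sum_projection`, `whole_cell_dextran`,
  `best_focus_plane`, `organelle_dextran`, `pearson_coloc`).
* **Superplot statistics** — cells → experiment means → grand mean ± 95%
  CI (t-based), and Holm–Šidák step-down multiple-comparison adjustment
  (`nested_summary`, `holm_sidak`).

## Worked example

```r
library(pinoquant)

# a synthetic cell: one 2-um macropinosome with six tubules, known truth
p <- scene_params(seed = 31, image_shape_px = c(128L, 128L),
                  n_vesicles_per_cell = 1L,
                  vesicle_diameter_um_range = c(2, 2),
                  n_tubules_per_vesicle = 6L,
                  noise = list(poisson_scale = 1, read_sigma = 2))
r <- render_scene(p)
mem <- get_plane(r$stack, 1, "membrane")
sig <- get_plane(r$stack, 1, "marker2")

cfg  <- analysis_config(threshold_method = "absolute",
                        absolute_threshold = 200)
mask <- segment_structures(mem, cfg)
tubs <- detect_tubules(mask$labels == 1L, analysis_config())
bg   <- cytoplasmic_background(sig,
          config = analysis_config(background_square_px = 30),
          cell_mask = r$truth$cell_masks > 0,
          exclude_mask = mask$labels > 0)
cl   <- classify_tubules(tubs, sig, bg)
cl$cell_fractions
#>       cell_id n_tubules n_positive fraction_positive
#> cell1   cell1         6          4         0.6666667

ctr <- snap_contour_to_ridge(mem, extract_contour(mask, 1L, 80))
tubulation_cv(contour_profile(mem, ctr, 3))
#> [1] 0.4701918
```

Six tubules are detected, four of which carry the secondary marker above
1.5× cytoplasm — matching the generator's ground truth
(`mean(r$truth$tubule_records$is_bright)` is 2/3). The circumferential CV
of ≈ 0.47 is far above the ≈ 0.01 measured on a plain ring: six
nucleation spots make the membrane profile strongly non-uniform.

A full command-line run of the same machinery:

```sh
Rscript inst/scripts/pinoquant simulate --seed 12 --out out/
Rscript inst/scripts/pinoquant track --in out/scene.tif --out out/
Rscript inst/scripts/pinoquant summarize --in out/track_metrics.csv --out out/
```

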