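# circle contour at exact ground-truth geometry, 1 px arc spacing
circle_contour <- function(center, radius_px, pixel_size_nm = 80,
                           diameter_um = 2 * radius_px * pixel_size_nm / 1000) {
  n <- max(8L, round(2 * pi * radius_px))
  th <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  membrane_contour(cbind(center[1] + radius_px * cos(th),
                         center[2] + radius_px * sin(th)),
                   diameter_um = diameter_um)
}

test_that("contour of a filled disc recovers the analytic diameter", {
  img <- disc_image(shape = c(64, 64), center = c(31, 31), radius = 10,
                    value = 100)
  m <- segment_structures(img, abs_config(50))
  ctr <- extract_contour(m, 1, pixel_size_nm = 80)
  expect_equal(ctr$diameter_um, 1.6, tolerance = 0.05 / 1.6)
  # ~1 px arc-length spacing
  steps <- sqrt(rowSums(diff(rbind(ctr$points, ctr$points[1, ]))^2))
  expect_true(all(abs(steps - 1) < 0.3))
})

test_that("contour length of a square approximates its perimeter", {
  lab <- matrix(0L, 40, 40)
  lab[10:29, 10:29] <- 1L
  ctr <- extract_contour(label_mask(lab), 1, 80)
  expect_equal(contour_length(ctr), 80, tolerance = 0.1)
})

test_that("degenerate structures are contour errors", {
  lab <- matrix(0L, 20, 20)
  lab[10, 10] <- 1L
  expect_error(extract_contour(label_mask(lab), 1, 80), "circumference|boundary")
  lab2 <- matrix(0L, 20, 20)
  lab2[1:6, 5:10] <- 1L                  # touches the border
  expect_error(extract_contour(label_mask(lab2), 1, 80), "border")
  expect_error(extract_contour(label_mask(lab), 2, 80), "not present")
})

test_that("contour profiles are exact on constant images", {
  ctr <- circle_contour(c(30, 30), 12)
  img <- matrix(7, 64, 64)
  pr1 <- contour_profile(img, ctr, width_px = 1)
  pr3 <- contour_profile(img, ctr, width_px = 3)
  expect_true(all(abs(pr1$values - 7) < 1e-9))
  expect_equal(pr1$values, pr3$values)
})

test_that("profile samples near the image edge are flagged missing", {
  ctr <- circle_contour(c(5, 30), 5)     # band reaches above row 0
  pr <- contour_profile(matrix(1, 40, 60), ctr, width_px = 5)
  expect_true(any(is.na(pr$values)))
  expect_false(all(is.na(pr$values)))
})

test_that("profile of a rendered ring matches the analytic band average", {
  p <- single_vesicle_scene(seed = 8, diameter_um = 1.6)
  r <- render_scene(p)
  mem <- r$stack$pixels[1, 1, , ]
  ves <- r$truth$vesicle_records
  ctr <- circle_contour(c(ves$center_row, ves$center_col), ves$radius_px)
  pr <- contour_profile(mem, ctr, width_px = 3)
  # analytic: cytoplasm + A * mean of the Gaussian cross-section at
  # offsets {-1, 0, 1} px from the ridge
  sig <- p$membrane_thickness_px
  band <- p$cytoplasm_level +
    p$membrane_intensity * (1 + 2 * exp(-1 / (2 * sig^2))) / 3
  expect_equal(mean(pr$values), band, tolerance = 0.05)
})

test_that("tubulation CV matches direct sd/mean evaluation", {
  expect_equal(tubulation_cv(line_profile(rep(5, 30))), 0)
  expect_equal(tubulation_cv(line_profile(c(8, 12))), sqrt(8) / 10)
  set.seed(42)
  for (i in 1:20) {
    v <- runif(sample(5:60, 1), 1, 100)
    expect_equal(tubulation_cv(line_profile(v)), sd(v) / mean(v),
                 tolerance = 1e-12)
  }
  # population-SD convention is a config switch
  v <- c(4, 8, 12)
  expect_equal(tubulation_cv(line_profile(v), 1,
                             analysis_config(cv_sd_denominator = "n")),
               sd(v) * sqrt(2 / 3) / mean(v), tolerance = 1e-12)
})

test_that("CV is gain-invariant and strictly increases with a raised sample", {
  set.seed(7)
  v <- runif(40, 10, 20)
  expect_equal(tubulation_cv(line_profile(v * 13.7)),
               tubulation_cv(line_profile(v)), tolerance = 1e-12)
  base <- rep(10, 40)
  raised <- base; raised[12] <- 25
  expect_gt(tubulation_cv(line_profile(raised)),
            tubulation_cv(line_profile(base)))
})

test_that("CV eligibility and degenerate profiles are errors", {
  pr <- line_profile(rep(5, 30), diameter_um = 0.8)
  expect_error(tubulation_cv(pr), "eligibility|minimum")
  expect_error(tubulation_cv(line_profile(rep(0, 10))), "zero")
  expect_error(tubulation_cv(line_profile(c(1, NA, NA))), "2 non-missing")
})

test_that("nucleation spots raise the circumferential CV, ordered by count", {
  cv_with_spots <- function(n_spots, seed) {
    p <- single_vesicle_scene(seed = seed, n_tubules = n_spots,
                              tubule_len = 9)
    r <- render_scene(p)
    mem <- r$stack$pixels[1, 1, , ]
    m <- segment_structures(mem, abs_config(200))
    ctr <- snap_contour_to_ridge(mem, extract_contour(m, 1, 80))
    tubulation_cv(contour_profile(mem, ctr, 3))
  }
  for (s in 1:3) {
    cv0 <- cv_with_spots(0, s); cv1 <- cv_with_spots(1, s)
    cv2 <- cv_with_spots(2, s)
    expect_lt(cv0, cv1)
    expect_lt(cv1, cv2)
  }
})

test_that("tubule detection respects the six-pixel length threshold", {
  render_and_detect <- function(len, seed = 3) {
    p <- single_vesicle_scene(seed = seed, diameter_um = 1.4,
                              n_tubules = 1, tubule_len = len,
                              spot_fold = 0)
    r <- render_scene(p)
    m <- segment_structures(r$stack$pixels[1, 1, , ], abs_config(200))
    detect_tubules(m$labels == 1L, analysis_config())
  }
  expect_length(render_and_detect(5), 0)     # "exceeded six pixels": 5 fails
  det10 <- render_and_detect(10)
  expect_length(det10, 1)
  expect_equal(det10[[1]]$length_px, 10, tolerance = 0.1)
  # plain annulus, no protrusions
  p <- single_vesicle_scene(seed = 4, n_tubules = 0)
  r <- render_scene(p)
  m <- segment_structures(r$stack$pixels[1, 1, , ], abs_config(200))
  expect_length(detect_tubules(m$labels == 1L, analysis_config()), 0)
})

test_that("cytoplasmic background measures the square mean", {
  img <- matrix(12, 120, 120)
  sq <- roi_annotation("square", vertices = rbind(c(10, 10), c(59, 59)))
  expect_equal(cytoplasmic_background(img, sq), 12)
  # strict mode rejects squares overlapping structures
  excl <- matrix(FALSE, 120, 120); excl[30, 30] <- TRUE
  expect_error(cytoplasmic_background(img, sq, exclude_mask = excl),
               "overlaps")
  expect_equal(suppressWarnings(
    cytoplasmic_background(img, sq, exclude_mask = excl, strict = FALSE)),
    12)
})

test_that("auto background placement recovers cytoplasm under noise", {
  p <- quiet_scene(seed = 15, noise = list(poisson_scale = 1, read_sigma = 2))
  r <- render_scene(p)
  sig <- r$stack$pixels[1, match("marker2", scene_channel_names), , ]
  excl <- r$truth$vesicle_label > 0 | r$truth$organelle_label > 0
  bg <- cytoplasmic_background(sig, config = analysis_config(
    background_square_px = 40), cell_mask = r$truth$cell_masks > 0,
    exclude_mask = excl)
  expect_equal(bg, p$cytoplasm_level, tolerance = 0.02)
  # impossible placement is an error
  expect_error(cytoplasmic_background(sig, config = analysis_config(
    background_square_px = 200)), "placement")
})

test_that("positivity boundary is inclusive at the fold threshold", {
  sk <- cbind(20L, 20:29)      # straight 10-px skeleton, 0-based
  tub <- list(list(tubule_id = 1L, root = c(20, 20), tip = c(20, 29),
                   skeleton_px = sk, length_px = 10))
  for (fold in c(1.40, 1.49, 1.499, 1.5, 1.501, 1.6)) {
    plane <- matrix(fold * 100, 50, 50)
    cl <- classify_tubules(tub, plane, background = 100)
    expect_identical(cl$calls$positive, fold >= 1.5)
  }
  # the classic boundary pair: 150 positive, 149 negative at background 100
  expect_true(classify_tubules(tub, matrix(150, 50, 50), 100)$calls$positive)
  expect_false(classify_tubules(tub, matrix(149, 50, 50), 100)$calls$positive)
  # zero-tubule cells get a missing fraction
  cl <- classify_tubules(list(), matrix(1, 5, 5), 1,
                         cell_ids = character())
  expect_equal(nrow(cl$calls), 0L)
  expect_error(classify_tubules(tub, matrix(1, 5, 5), 0), "> 0")
})

test_that("bright/dim tubule mixes give the ground-truth positive fraction", {
  p <- scene_params(seed = 31, image_shape_px = c(128L, 128L), n_cells = 1L,
                    n_vesicles_per_cell = 1L,
                    vesicle_diameter_um_range = c(2, 2),
                    n_tubules_per_vesicle = 6L,
                    tubule_length_px_range = c(9, 14),
                    bright_tubule_prob = 0.5,
                    noise = list(poisson_scale = 0, read_sigma = 0))
  r <- render_scene(p)
  mem <- r$stack$pixels[1, 1, , ]
  sig <- r$stack$pixels[1, match("marker2", scene_channel_names), , ]
  m <- segment_structures(mem, abs_config(200))
  tubs <- detect_tubules(m$labels == 1L, analysis_config())
  gt <- r$truth$tubule_records
  expect_length(tubs, nrow(gt))
  cl <- classify_tubules(tubs, sig, background = p$cytoplasm_level)
  expect_equal(cl$cell_fractions$fraction_positive, mean(gt$is_bright))
})

test_that("profile alignment puts the reference peak at the centre index", {
  v <- rep(50, 21); v[8] <- 150          # peak at 0-based index 7
  agg <- align_and_normalize_profiles(list(line_profile(v)))
  expect_equal(agg$profiles[[1]]$alignment_offset, 3L)
  expect_equal(agg$center_index, 10L)
  expect_equal(which.max(agg$mean[, 1]) - 1L, 10L)
  # fold-change: peak 150 over off-window 50 normalizes to 3
  expect_equal(max(agg$mean[, 1], na.rm = TRUE), 3)
})

test_that("aligned profiles have off-window mean 1 and alignment idempotence", {
  set.seed(9)
  profs <- lapply(1:6, function(i) {
    v <- runif(25, 40, 60); v[6 + i] <- 200
    line_profile(v)
  })
  agg <- align_and_normalize_profiles(profs)
  halfw <- (analysis_config()$profile_exclusion_window_px - 1) / 2
  out_win <- abs(agg$positions - agg$center_index) > halfw
  for (pr in agg$profiles)
    expect_equal(mean(pr$values[out_win, 1], na.rm = TRUE), 1,
                 tolerance = 1e-6)
  # aligning the aligned set changes nothing
  agg2 <- align_and_normalize_profiles(agg$profiles)
  expect_equal(vapply(agg2$profiles, `[[`, 1L, "alignment_offset"),
               rep(0L, 6))
  expect_equal(agg2$mean, agg$mean)
})

test_that("pre-shifted identical profiles aggregate to the original", {
  base <- rep(50, 25); base[13] <- 150; base[12] <- 100; base[14] <- 100
  shift_by <- function(v, k) {
    out <- rep(50, length(v))
    src <- seq_along(v) - k
    ok <- src >= 1 & src <= length(v)
    out[ok] <- v[src[ok]]
    out
  }
  agg <- align_and_normalize_profiles(list(line_profile(shift_by(base, 2)),
                                           line_profile(shift_by(base, -2))))
  both <- agg$n[, 1] == 2
  expect_equal(agg$mean[both, 1], base[both] / 50)
  expect_true(all(agg$ci_half_width[both, 1] == 0))
})

test_that("profiles shorter than the exclusion window are rejected", {
  expect_error(align_and_normalize_profiles(list(line_profile(rep(1, 10)))),
               "shorter")
  expect_error(align_and_normalize_profiles(list()), "at least one")
})
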