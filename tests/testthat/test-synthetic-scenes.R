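test_that("renders are bit-reproducible under a fixed seed", {
  p <- quiet_scene(seed = 11, noise = list(poisson_scale = 1, read_sigma = 2))
  r1 <- render_scene(p)
  r2 <- render_scene(p)
  expect_identical(r1$stack$pixels, r2$stack$pixels)
  expect_identical(r1$truth$vesicle_records, r2$truth$vesicle_records)
})

test_that("every requested structure gets exactly one ground-truth record", {
  p <- scene_params(seed = 2, image_shape_px = c(320L, 320L), n_cells = 2L,
                    n_vesicles_per_cell = 3L,
                    vesicle_diameter_um_range = c(0.6, 1.4),
                    n_organelles = 8L,
                    noise = list(poisson_scale = 0, read_sigma = 0))
  r <- render_scene(p)
  expect_equal(nrow(r$truth$vesicle_records), 6L)
  expect_equal(nrow(r$truth$organelle_records), 8L)
  expect_setequal(unique(r$truth$vesicle_records$cell_id), c(1L, 2L))
})

test_that("noise-free dextran render matches the recorded lumen sums", {
  r <- render_scene(quiet_scene(seed = 4, n_organelles = 6L))
  dex <- r$truth$noise_free_channels[1, match("dextran", scene_channel_names), , ]
  cyto <- r$truth$params$cytoplasm_level
  org <- r$truth$organelle_records
  for (i in seq_len(nrow(org))) {
    idx <- which(r$truth$organelle_label == org$id[i])
    # rendered = cytoplasm + lumen fill over exactly the recorded pixels
    expect_equal(sum(dex[idx]) - cyto * length(idx),
                 org$lumen_dextran_sum[i])
  }
})

test_that("whole-cell dextran is conserved: lumen fills plus cytoplasm", {
  r <- render_scene(quiet_scene(seed = 9, n_organelles = 4L))
  tr <- r$truth
  dex <- tr$noise_free_channels[1, match("dextran", scene_channel_names), , ]
  in_cell <- tr$cell_masks > 0
  expected <- tr$params$cytoplasm_level * sum(in_cell) +
    sum(tr$organelle_records$lumen_dextran_sum) +
    sum(vapply(tr$vesicle_lumens, nrow, 1L)) * tr$params$dextran_lumen_level
  expect_equal(sum(dex[in_cell]), expected)
})

test_that("infeasible packing raises a generation error", {
  expect_error(scene_params(image_shape_px = c(64L, 64L),
                            vesicle_diameter_um_range = c(3, 3)),
               "too small")
  p <- quiet_scene(seed = 1)
  p$n_vesicles_per_cell <- 60L   # cannot fit without overlap
  expect_error(render_scene(p), "packing")
})

test_that("noise model is seeded, unbiased and has Poisson variance", {
  img <- matrix(50, 120, 120)
  n1 <- add_noise(img, poisson_scale = 1, read_sigma = 0, seed = 5)
  n2 <- add_noise(img, poisson_scale = 1, read_sigma = 0, seed = 5)
  expect_identical(n1, n2)
  # variance of Poisson(L * s) / s is L / s
  for (s in c(1, 4)) {
    n <- add_noise(img, poisson_scale = s, read_sigma = 0, seed = 7)
    expect_equal(var(as.vector(n)), 50 / s, tolerance = 0.1)
    expect_equal(mean(n), 50, tolerance = 0.05)
  }
  # large photon gain approaches the noise-free limit
  hi <- add_noise(img, poisson_scale = 1e6, read_sigma = 0, seed = 3)
  lo <- add_noise(img, poisson_scale = 1e2, read_sigma = 0, seed = 3)
  expect_lt(max(abs(hi - img)), max(abs(lo - img)))
  expect_lt(max(abs(hi - img)), 0.05)
  expect_error(add_noise(img, -1, 0, 1), "non-negative")
  expect_error(add_noise(img - 100, 1, 0, 1), "non-negative")
})

test_that("maturation probability extremes force the recorded fates", {
  base <- quiet_scene(seed = 3, image_shape_px = c(256L, 256L))
  for (p_succ in c(0, 1)) {
    tp <- timelapse_params(scene = base, n_frames = 20,
                           birth_rate_per_cell_per_min = 6,
                           maturation_success_prob = p_succ)
    r <- render_timelapse(tp)
    vr <- r$truth$vesicle_records
    new <- vr[!vr$present_at_start, ]
    expect_gt(nrow(new), 0)
    expect_true(all(new$fate == if (p_succ == 1) "success" else "failure"))
    if (p_succ == 0) {
      # failed vesicles never carry maturation marker above cytoplasm
      m2 <- r$truth$noise_free_channels[, match("marker2",
                                                scene_channel_names), , ]
      expect_lte(max(m2), r$truth$params$cytoplasm_level + 1e-9)
    }
  }
})

test_that("birth counts follow the Poisson rate", {
  # 2 births/cell/min for 5 min in 4 cells = 40 expected per movie
  tot <- vapply(1:20, function(s) {
    p <- scene_params(seed = s, image_shape_px = c(340L, 340L), n_cells = 4L,
                      vesicle_diameter_um_range = c(0.9, 1.2),
                      noise = list(poisson_scale = 0, read_sigma = 0))
    tp <- timelapse_params(scene = p, n_frames = 101, frame_interval_s = 3,
                           birth_rate_per_cell_per_min = 2,
                           maturation_success_prob = 1)
    r <- render_timelapse(tp)
    vr <- r$truth$vesicle_records
    if (is.null(vr)) 0L else sum(!vr$present_at_start)
  }, 1L)
  expected <- 2 * 5 * 4
  se <- sqrt(expected / 20)      # SE of the mean of 20 Poisson movies
  expect_lt(abs(mean(tot) - expected), 3 * se)
})

test_that("empirical success fraction recovers the generative probability", {
  fr <- vapply(1:20, function(s) {
    p <- scene_params(seed = s, image_shape_px = c(256L, 256L),
                      vesicle_diameter_um_range = c(0.9, 1.3),
                      noise = list(poisson_scale = 0, read_sigma = 0))
    tp <- timelapse_params(scene = p, n_frames = 30,
                           birth_rate_per_cell_per_min = 8,
                           maturation_success_prob = 0.5)
    vr <- render_timelapse(tp)$truth$vesicle_records
    new <- vr[!vr$present_at_start, ]
    c(sum(new$fate == "success"), nrow(new))
  }, c(1, 1))
  phat <- sum(fr[1, ]) / sum(fr[2, ])
  se <- sqrt(0.5 * 0.5 / sum(fr[2, ]))
  expect_lt(abs(phat - 0.5), 3 * se)
})

test_that("tubule ground truth matches the rendered geometry", {
  r <- render_scene(single_vesicle_scene(seed = 6, n_tubules = 2,
                                         tubule_len = 12))
  tub <- r$truth$tubule_records
  expect_equal(nrow(tub), 2L)
  # recorded root sits on the annulus: |root - center| = ring radius
  ves <- r$truth$vesicle_records
  d <- sqrt((tub$root_row - ves$center_row)^2 +
            (tub$root_col - ves$center_col)^2)
  expect_equal(d, rep(ves$radius_px, 2), tolerance = 1e-9)
  expect_equal(sqrt((tub$tip_row - tub$root_row)^2 +
                    (tub$tip_col - tub$root_col)^2),
               tub$length_px, tolerance = 1e-9)
})

test_that("ground truth serializes to JSON and label TIFFs", {
  r <- render_scene(quiet_scene(seed = 12))
  dir <- withr::local_tempdir()
  write_ground_truth(r$truth, dir)
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(nrow(gt$vesicle_records), nrow(r$truth$vesicle_records))
  lab <- round(tiff::readTIFF(file.path(dir, "cell_masks.tif")) * 65535)
  expect_identical(lab, r$truth$cell_masks * 1)
})
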