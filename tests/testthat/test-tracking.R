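test_that("a blank movie yields no detections", {
  stk <- frames_stack(list(matrix(1, 40, 40), matrix(1, 40, 40)))
  det <- detect_per_frame(stk, 1L, abs_config(10))
  expect_equal(nrow(det), 0L)
  expect_length(link_tracks(det, 80, analysis_config()), 0)
})

test_that("the equivalent radius follows the area formula for solid blobs", {
  img <- matrix(0, 50, 50)
  img[10:17, 10:19] <- 500               # 80 px
  img[10, 10] <- 0                       # exactly 79 px
  stk <- frames_stack(list(img, img), pixel_size_nm = 80)
  det <- detect_per_frame(stk, 1L, abs_config(100))
  expect_equal(det$area_px, c(79L, 79L))
  expect_equal(det$equivalent_radius_nm, rep(sqrt(79 / pi) * 80, 2))
  expect_equal(round(det$equivalent_radius_nm[1]), 401)
})

test_that("ring detections report the membrane-centerline radius", {
  p <- single_vesicle_scene(seed = 17, diameter_um = 1.6)
  r <- render_scene(p)
  stk <- frames_stack(list(r$stack$pixels[1, 1, , ],
                           r$stack$pixels[1, 1, , ]))
  det <- detect_per_frame(stk, 1L, abs_config(120))
  gt_r_nm <- r$truth$vesicle_records$radius_px * 80
  expect_equal(nrow(det), 2L)
  expect_lt(abs(det$equivalent_radius_nm[1] - gt_r_nm), 80)  # within 1 px
})

test_that("a drifting vesicle links into a single track", {
  det <- data.frame(frame = 1:10, structure_id = 1L,
                    centroid_row = 50 + (1:10), centroid_col = 50,
                    area_px = 100L, equivalent_radius_nm = 450)
  tracks <- link_tracks(det, 80, analysis_config())
  expect_length(tracks, 1)
  expect_equal(nrow(tracks[[1]]$detections), 10L)
  expect_equal(tracks[[1]]$born_at_frame, 1L)
  expect_true(tracks[[1]]$present_at_start)
})

test_that("well-separated stationary vesicles never swap tracks", {
  det <- do.call(rbind, lapply(1:8, function(f)
    data.frame(frame = f, structure_id = 1:2,
               centroid_row = c(20, 70), centroid_col = 30,
               area_px = 100L, equivalent_radius_nm = 450)))
  tracks <- link_tracks(det, 80, analysis_config())
  expect_length(tracks, 2)
  for (tr in tracks)
    expect_equal(diff(range(tr$detections$centroid_row)), 0)
})

test_that("linking bridges gaps up to max_gap and is order-invariant", {
  det <- data.frame(frame = c(1, 2, 4, 5), structure_id = 1L,
                    centroid_row = 50, centroid_col = c(50, 51, 53, 54),
                    area_px = 100L, equivalent_radius_nm = 450)
  tracks <- link_tracks(det, 80, analysis_config())
  expect_length(tracks, 1)      # frame-3 gap bridged
  tracks2 <- link_tracks(det, 80, analysis_config(max_gap = 0L))
  expect_length(tracks2, 2)     # no gap closing

  # permutation of within-frame detection order does not change the partition
  det2 <- do.call(rbind, lapply(1:6, function(f)
    data.frame(frame = f, structure_id = 1:3,
               centroid_row = c(20, 45, 70) + f * 0.3,
               centroid_col = c(30, 60, 20),
               area_px = 100L, equivalent_radius_nm = 450)))
  set.seed(1)
  det2_shuf <- do.call(rbind, lapply(split(det2, det2$frame),
                                     function(d) d[sample(nrow(d)), ]))
  key <- function(tracks) sort(vapply(tracks, function(tr)
    paste(round(tr$detections$centroid_row), collapse = ","), ""))
  expect_equal(key(link_tracks(det2_shuf, 80, analysis_config())),
               key(link_tracks(det2, 80, analysis_config())))
})

test_that("newly-formed filters drop small and pre-existing tracks", {
  tracks <- list(
    make_track("small", 2:6, rep(350, 5)),          # median < 400 nm
    make_track("early", 1:6, rep(500, 6)),          # present at start
    make_track("good1", 2:7, rep(500, 6)),
    make_track("good2", 3:8, c(390, 410, 500, 500, 500, 500)),
    make_track("good3", 5:9, rep(450, 5)))
  kept <- filter_new_tracks(tracks, analysis_config())
  expect_equal(vapply(kept, `[[`, "", "track_id"),
               c("good1", "good2", "good3"))  # subset, order preserved
})

test_that("track metrics follow their stated arithmetic", {
  tracks <- lapply(1:6, function(i) make_track(paste0("t", i), 2:5,
                                               rep(600, 4)))
  met <- track_metrics(tracks, duration_min = 5, n_cells = 2)
  expect_equal(met$frequency_per_cell_per_min, 0.6)
  expect_equal(met$diameters_um, rep(1.2, 6))
  empty <- track_metrics(list(), 5, 2)
  expect_equal(empty$frequency_per_cell_per_min, 0)
  expect_length(empty$diameters_um, 0)
  expect_error(track_metrics(tracks, 0, 1), "> 0")
})

test_that("maturation fates follow the marker and termination rules", {
  px <- array(1, dim = c(20, 2, 10, 10))
  stk <- image_stack(px, "time", channel_names = c("marker2", "pm"))
  cfg <- analysis_config()               # success: >= 1.5x bg, 2 frames
  succ <- make_track("s", 3:8, rep(500, 6),
                     marker_means = c(80, 80, 200, 200, 90, 90))
  fail <- make_track("f", 3:8, rep(500, 6),
                     marker_means = rep(80, 6))
  cens <- make_track("c", 15:20, rep(500, 6),
                     marker_means = rep(80, 6))
  blip <- make_track("b", 3:8, rep(500, 6),
                     marker_means = c(80, 200, 80, 200, 80, 80))
  expect_equal(classify_maturation(succ, stk, 100, cfg), "success")
  expect_equal(classify_maturation(fail, stk, 100, cfg), "failure")
  expect_equal(classify_maturation(cens, stk, 100, cfg), "censored")
  # a single-frame blip does not count as acquisition
  expect_equal(classify_maturation(blip, stk, 100, cfg), "failure")

  no_pm <- image_stack(px, "time", channel_names = c("marker2", "other"))
  expect_error(classify_maturation(succ, no_pm, 100, cfg),
               "plasma-membrane")

  rate <- maturation_success_rate(c("success", "failure", "success",
                                    "censored"))
  expect_equal(rate$success_rate, 2 / 3)
  expect_true(is.na(maturation_success_rate(c("censored"))$success_rate))
})

test_that("synthetic movies round-trip through the full tracking chain", {
  p <- scene_params(seed = 23, image_shape_px = c(256L, 256L),
                    vesicle_diameter_um_range = c(1.0, 1.8),
                    noise = list(poisson_scale = 1, read_sigma = 2))
  tp <- timelapse_params(scene = p, n_frames = 30,
                         birth_rate_per_cell_per_min = 4,
                         maturation_success_prob = 0.5,
                         n_initial_vesicles = 2L)
  r <- render_timelapse(tp)
  cfg <- abs_config(90)
  det <- detect_per_frame(r$stack, "membrane", cfg)
  tracks <- link_tracks(det, r$stack$pixel_size_nm, cfg)
  kept <- filter_new_tracks(tracks, cfg)
  gt <- r$truth$vesicle_records
  gt_new <- gt[!gt$present_at_start, ]
  expect_lte(abs(length(kept) - nrow(gt_new)), 1)
  bg <- median(r$stack$pixels[1, 2, , ][r$truth$cell_masks > 0])
  fates <- vapply(kept, function(tr)
    classify_maturation(tr, r$stack, bg, cfg), "")
  # births close to the movie end are measured censored even when the
  # generative fate is success; compare on the unambiguous early births
  expect_lte(abs(sum(fates == "success") -
                 sum(gt_new$fate == "success")), 1)
})
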