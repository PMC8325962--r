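test_that("image stacks validate their invariants", {
  px <- array(runif(2 * 2 * 8 * 8), dim = c(2, 2, 8, 8))
  s <- image_stack(px, "time", pixel_size_nm = 80, frame_interval_s = 3,
                   channel_names = c("a", "b"))
  expect_s3_class(s, "image_stack")
  expect_equal(dim(s), c(2L, 2L, 8L, 8L))
  expect_error(image_stack(px, "time", channel_names = "a"), "channel_names")
  expect_error(image_stack(px * -1), "non-negative")
  expect_error(image_stack(px, pixel_size_nm = 0), "pixel_size_nm")
  px[1] <- NA
  expect_error(image_stack(px), "finite")
  # matrices are promoted to single-plane single-channel stacks
  expect_equal(dim(image_stack(matrix(1, 4, 5))), c(1L, 1L, 4L, 5L))
})

test_that("integer TIFF stacks round-trip bit-exactly with calibration", {
  px <- array(sample(0:4095, 2 * 2 * 16 * 16, replace = TRUE),
              dim = c(2, 2, 16, 16))
  s <- image_stack(px, "time", pixel_size_nm = 80, frame_interval_s = 3,
                   channel_names = c("mem", "marker"))
  path <- file.path(withr::local_tempdir(), "stack.tif")
  write_image_stack(s, path)
  r <- read_image_stack(path)
  expect_identical(r$pixels, s$pixels * 1)
  expect_equal(r$pixel_size_nm, 80)
  expect_equal(r$frame_interval_s, 3)
  expect_equal(r$channel_names, c("mem", "marker"))
})

test_that("float stacks and z-stacks round-trip through TIFF", {
  px <- array(runif(3 * 1 * 8 * 8) * 1234, dim = c(3, 1, 8, 8))
  s <- image_stack(px, "z", z_step_nm = 250)
  path <- file.path(withr::local_tempdir(), "z.tif")
  write_image_stack(s, path)
  r <- read_image_stack(path)
  expect_equal(r$axis_kind, "z")
  expect_equal(r$z_step_nm, 250)
  expect_equal(r$pixels, s$pixels, tolerance = 1e-6)
})

test_that("reading a missing or malformed image file is an error", {
  expect_error(read_image_stack("no/such/file.tif"), "not found")
  # inconsistent page shapes are reported with the offending page
  f <- file.path(withr::local_tempdir(), "bad.tif")
  tiff::writeTIFF(list(matrix(0.5, 4, 4), matrix(0.5, 5, 4)), f)
  expect_error(read_image_stack(f), "page 2")
})

test_that("ROI annotations load from CSV with defaults and bounds checks", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "rois.csv")
  writeLines("kind,frame,label,width_px,vertices", f)
  expect_length(load_roi_annotations(f), 0)

  writeLines(c("kind,frame,label,width_px,vertices",
               "line,0,t1,3,10:12;20:30",
               "line,1,t2,NA,5:5;6:9"), f)
  rois <- load_roi_annotations(f)
  expect_length(rois, 2)
  expect_equal(rois[[1]]$width_px, 3L)
  expect_equal(rois[[1]]$vertices[2, ], c(row = 20, col = 30))
  # absent width falls back to the three-pixel profile convention
  expect_equal(rois[[2]]$width_px, 3L)

  writeLines(c("kind,frame,label,width_px,vertices",
               "line,0,bad,3,-1:5;4:4"), f)
  expect_error(load_roi_annotations(f), "record 1")
  writeLines(c("kind,frame,label,width_px,vertices",
               "line,0,oob,3,2:2;40:2"), f)
  expect_error(load_roi_annotations(f, image_shape = c(20, 20)), "bounds")
})

test_that("ROI annotations load from JSON equivalently", {
  f <- file.path(withr::local_tempdir(), "rois.json")
  jsonlite::write_json(list(list(kind = "line", frame = 0, label = "t1",
                                 width_px = 3,
                                 vertices = list(c(1, 2), c(3, 4)))),
                       f, auto_unbox = TRUE)
  rois <- load_roi_annotations(f)
  expect_length(rois, 1)
  expect_equal(rois[[1]]$vertices[1, ], c(row = 1, col = 2))
})

test_that("measurement tables round-trip CSV including the NA sentinel", {
  tab <- measurement_table(scope = c("cell", "cell", "tubule"),
                           cell_id = c("c1", "c2", "c1"),
                           experiment_id = "E1",
                           metric_name = "m",
                           value = c(1.5, NA, -2.25))
  path <- file.path(withr::local_tempdir(), "m.csv")
  write_measurements(tab, path)
  expect_true(any(grepl("NA", readLines(path)[3])))
  back <- read_measurements(path)
  expect_equal(as.data.frame(back), as.data.frame(tab))

  empty <- measurement_table()
  write_measurements(empty, path)
  expect_length(readLines(path), 1)   # header only
  expect_equal(nrow(read_measurements(path)), 0L)
})

test_that("analysis config enforces invariants and YAML round-trips", {
  cfg <- analysis_config()
  expect_equal(cfg$min_structure_area_px, 5L)
  expect_equal(cfg$tubule_min_length_px, 6L)
  expect_equal(cfg$positive_fold_threshold, 1.5)
  expect_equal(cfg$background_square_px, 100L)
  expect_equal(cfg$profile_exclusion_window_px, 15L)
  expect_equal(cfg$membrane_roi_diameter_px, 10L)
  expect_equal(cfg$trace_align_time_s, 15)
  expect_equal(cfg$min_track_radius_nm, 400)
  expect_error(analysis_config(profile_exclusion_window_px = 14), "odd")
  expect_error(analysis_config(min_structure_area_px = 0), "positive")
  expect_error(analysis_config(threshold_method = "absolute"),
               "absolute_threshold")

  f <- file.path(withr::local_tempdir(), "cfg.yaml")
  write_config(analysis_config(tubule_min_length_px = 8), f)
  expect_equal(read_config(f)$tubule_min_length_px, 8L)
  writeLines("not_a_field: 3", f)
  expect_error(read_config(f), "unknown configuration field")
})

test_that("physical quantities scale with calibration, pixel ones do not", {
  img <- disc_image(radius = 12, value = 500)
  cfg <- abs_config(100)
  for (pxnm in c(80, 160)) {
    stk <- image_stack(img, "time", pixel_size_nm = pxnm)
    det <- detect_per_frame(stk, 1L, cfg)
    expect_equal(det$area_px, det$area_px[1])   # pixel-level unchanged
    expect_equal(det$equivalent_radius_nm,
                 sqrt(det$area_px / pi) * pxnm)  # physical scales
  }
})
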