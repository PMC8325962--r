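# Shared fixture builders; everything is generated in code at test time.

# config with an absolute threshold, the usual choice for noise-free renders
abs_config <- function(threshold, ...) {
  analysis_config(threshold_method = "absolute",
                  absolute_threshold = threshold, ...)
}

# a quiet single-cell scene: no noise unless asked for
quiet_scene <- function(seed = 1, image_shape_px = c(160L, 160L),
                        vesicle_diameter_um_range = c(0.8, 1.6), ...,
                        noise = list(poisson_scale = 0, read_sigma = 0)) {
  scene_params(seed = seed, image_shape_px = image_shape_px, n_cells = 1L,
               vesicle_diameter_um_range = vesicle_diameter_um_range,
               noise = noise, ...)
}

# one vesicle of fixed diameter with a controlled tubule configuration
single_vesicle_scene <- function(seed = 1, diameter_um = 1.6, n_tubules = 0,
                                 tubule_len = 10, spot_fold = 1.5,
                                 bright_prob = 0.5,
                                 noise = list(poisson_scale = 0,
                                              read_sigma = 0), ...) {
  scene_params(seed = seed, image_shape_px = c(128L, 128L), n_cells = 1L,
               n_vesicles_per_cell = n_tubules * 0 + 1L,
               vesicle_diameter_um_range = c(diameter_um, diameter_um),
               n_tubules_per_vesicle = n_tubules,
               tubule_length_px_range = c(tubule_len, tubule_len),
               nucleation_spot_fold = spot_fold,
               bright_tubule_prob = bright_prob,
               noise = noise, ...)
}

# synthetic image: a hard-edged disc of given value on a constant background
disc_image <- function(shape = c(64L, 64L), center = c(31, 31), radius = 10,
                       value = 100, background = 0) {
  img <- matrix(background, shape[1], shape[2])
  idx <- which(outer((seq_len(shape[1]) - 1 - center[1])^2,
                     (seq_len(shape[2]) - 1 - center[2])^2, "+") <= radius^2)
  img[idx] <- value
  img
}

# a minimal single-channel time stack from a list of frame matrices
frames_stack <- function(frames, pixel_size_nm = 80, frame_interval_s = 3,
                         channel_names = "ch1") {
  d <- dim(frames[[1]])
  px <- array(0, dim = c(length(frames), 1, d[1], d[2]))
  for (f in seq_along(frames)) px[f, 1, , ] <- frames[[f]]
  image_stack(px, axis_kind = "time", pixel_size_nm = pixel_size_nm,
              frame_interval_s = frame_interval_s,
              channel_names = channel_names)
}

# hand-built track in the format link_tracks() emits
make_track <- function(id, frames, radii_nm, marker_means = NULL,
                       rows = NULL, cols = NULL, first_movie_frame = 1L) {
  det <- data.frame(frame = frames,
                    centroid_row = rows %||% rep(50, length(frames)),
                    centroid_col = cols %||% rep(50, length(frames)),
                    area_px = 50L,
                    equivalent_radius_nm = radii_nm)
  if (!is.null(marker_means)) det$mean_marker2 <- marker_means
  list(track_id = id, detections = det, born_at_frame = frames[1],
       present_at_start = frames[1] == first_movie_frame,
       fate = "unclassified")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
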