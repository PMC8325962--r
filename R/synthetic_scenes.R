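# Synthetic multi-channel fluorescence scenes with exact ground truth.
#
# Scenes emulate the statistical structure the quantification assumes:
# cells with cytoplasmic background, ring-shaped macropinosome limiting
# membranes (Gaussian cross-section annuli), tubule protrusions rooted at
# bright nucleation spots on the ring, punctate organelles, diffuse lumenal
# dextran, a plasma-membrane outline channel, and Poisson shot noise plus
# Gaussian read noise. Five channels are rendered, in order:
#   membrane  - limiting-membrane marker: rings, nucleation spots, tubules
#   marker2   - secondary marker, tubule-enriched for bright tubules
#               (in time-lapses: the PtdIns3P maturation marker on rings)
#   organelle - punctate organelle marker
#   dextran   - fluid-phase cargo: vesicle and organelle lumen fill
#   pm        - plasma-membrane outline of each cell

#' Channel order of synthetic scenes
#'
#' The five channels every synthetic render contains, in stack order:
#' membrane marker, secondary/maturation marker, organelle marker, dextran
#' (fluid phase), plasma membrane.
#' @export
scene_channel_names <- c("membrane", "marker2", "organelle", "dextran", "pm")

#' Parameters of a synthetic microscopy scene
#'
#' Defaults describe the imaging regime the pipeline targets: 80 nm/px
#' sampling, macropinosome diameters 0.4-3 um, thin (about 1.5 px sigma)
#' membrane cross-sections, tubules 8-16 px long, and shot plus read noise
#' at comfortable SNR.
#'
#' @param image_shape_px \code{c(rows, cols)} of the rendered field.
#' @param pixel_size_nm Lateral calibration (nm per pixel).
#' @param n_cells Number of cells, placed on a jittered grid without overlap.
#' @param cytoplasm_level Cytoplasmic background intensity inside cells.
#' @param n_vesicles_per_cell Integer count or \code{c(min, max)} range.
#' @param vesicle_diameter_um_range \code{c(min, max)} diameter in um.
#' @param membrane_intensity Peak ring amplitude of the membrane channel.
#' @param membrane_thickness_px Gaussian sigma of the ring cross-section.
#' @param n_tubules_per_vesicle Integer count or \code{c(min, max)} range.
#' @param tubule_length_px_range \code{c(min, max)} tubule length in px.
#' @param tubule_intensity_fold Secondary-marker intensity of a bright
#'   tubule, as a fold of \code{cytoplasm_level}.
#' @param dim_tubule_fold Secondary-marker fold of a dim tubule.
#' @param bright_tubule_prob Probability a tubule is secondary-marker bright.
#' @param nucleation_spot_fold Membrane-channel amplitude of the nucleation
#'   spot at each tubule root, as a fold of \code{membrane_intensity}.
#' @param n_organelles Punctate organelles per scene (inside cells).
#' @param organelle_diameter_px_range \code{c(min, max)} in px.
#' @param organelle_intensity Organelle-channel level inside puncta.
#' @param dextran_lumen_level Dextran-channel level inside vesicle and
#'   organelle lumens.
#' @param noise List \code{(poisson_scale, read_sigma)}; see
#'   \code{\link{add_noise}}. \code{poisson_scale = 0} disables shot noise.
#' @param seed Integer RNG seed; renders are bit-reproducible given the seed.
#' @return An object of class \code{scene_params}.
#' @export
scene_params <- function(image_shape_px = c(256L, 256L),
                         pixel_size_nm = 80,
                         n_cells = 1L,
                         cytoplasm_level = 40,
                         n_vesicles_per_cell = 3L,
                         vesicle_diameter_um_range = c(0.4, 3),
                         membrane_intensity = 400,
                         membrane_thickness_px = 1.5,
                         n_tubules_per_vesicle = c(0L, 2L),
                         tubule_length_px_range = c(8, 16),
                         tubule_intensity_fold = 3,
                         dim_tubule_fold = 1.1,
                         bright_tubule_prob = 0.5,
                         nucleation_spot_fold = 1.5,
                         n_organelles = 12L,
                         organelle_diameter_px_range = c(3, 6),
                         organelle_intensity = 200,
                         dextran_lumen_level = 100,
                         noise = list(poisson_scale = 1, read_sigma = 2),
                         seed = 1L) {
  p <- list(image_shape_px = as.integer(image_shape_px),
            pixel_size_nm = pixel_size_nm, n_cells = as.integer(n_cells),
            cytoplasm_level = cytoplasm_level,
            n_vesicles_per_cell = n_vesicles_per_cell,
            vesicle_diameter_um_range = vesicle_diameter_um_range,
            membrane_intensity = membrane_intensity,
            membrane_thickness_px = membrane_thickness_px,
            n_tubules_per_vesicle = n_tubules_per_vesicle,
            tubule_length_px_range = tubule_length_px_range,
            tubule_intensity_fold = tubule_intensity_fold,
            dim_tubule_fold = dim_tubule_fold,
            bright_tubule_prob = bright_tubule_prob,
            nucleation_spot_fold = nucleation_spot_fold,
            n_organelles = as.integer(n_organelles),
            organelle_diameter_px_range = organelle_diameter_px_range,
            organelle_intensity = organelle_intensity,
            dextran_lumen_level = dextran_lumen_level,
            noise = noise, seed = as.integer(seed))
  validate_scene_params(p)
  structure(p, class = "scene_params")
}

validate_scene_params <- function(p) {
  if (length(p$image_shape_px) != 2 || any(p$image_shape_px < 32))
    stop("image_shape_px must be two values >= 32", call. = FALSE)
  for (nm in c("vesicle_diameter_um_range", "tubule_length_px_range",
               "organelle_diameter_px_range")) {
    r <- p[[nm]]
    if (length(r) != 2 || r[1] > r[2] || any(r <= 0))
      stop(nm, " must be an ordered positive (min, max) pair", call. = FALSE)
  }
  lv <- c(p$cytoplasm_level, p$membrane_intensity, p$dextran_lumen_level,
          p$organelle_intensity)
  if (any(lv < 0)) stop("intensity levels must be >= 0", call. = FALSE)
  if (p$bright_tubule_prob < 0 || p$bright_tubule_prob > 1)
    stop("bright_tubule_prob must be in [0, 1]", call. = FALSE)
  if (p$noise$poisson_scale < 0 || p$noise$read_sigma < 0)
    stop("noise parameters must be >= 0", call. = FALSE)
  # feasibility: cells on a grid must leave room for the largest vesicle
  gr <- ceiling(sqrt(p$n_cells))
  cell_r <- floor(min(p$image_shape_px / gr) / 2) - 4
  max_ves_r <- p$vesicle_diameter_um_range[2] * 1000 / p$pixel_size_nm / 2
  if (cell_r < max_ves_r + max(p$tubule_length_px_range) + 4)
    stop("image too small to contain the requested cells and vesicles",
         call. = FALSE)
  invisible(p)
}

#' Parameters of a synthetic time-lapse
#'
#' Extends \code{\link{scene_params}} with birth/maturation dynamics:
#' vesicles are born at Poisson times, succeed (acquire the maturation
#' marker and persist) with probability \code{maturation_success_prob} or
#' fail (vanish back into the plasma membrane after
#' \code{failure_lifetime_frames} without marker acquisition), and carry a
#' biphasic membrane-marker recruitment envelope peaking at
#' \code{biphasic_peak_frames}.
#'
#' @param scene A \code{scene_params} object for the static geometry
#'   (its \code{n_vesicles_per_cell} is ignored; births are stochastic).
#' @param n_frames Number of frames (>= 2).
#' @param frame_interval_s Seconds between frames.
#' @param birth_rate_per_cell_per_min Poisson birth rate of new vesicles.
#' @param maturation_success_prob Probability a vesicle matures.
#' @param marker_onset_frame Frames after birth at which a successful
#'   vesicle acquires the maturation marker.
#' @param biphasic_peak_frames \code{c(first, second)} peaks (frames after
#'   birth) of the membrane-marker envelope.
#' @param failure_lifetime_frames Lifetime of a failing vesicle (frames).
#' @param n_initial_vesicles Vesicles already present at frame 1
#'   (excluded by the newly-formed filter downstream).
#' @param motion_sigma_px Per-frame Gaussian centroid jitter (px).
#' @return An object of class \code{timelapse_params}.
#' @export
timelapse_params <- function(scene = scene_params(),
                             n_frames = 40L,
                             frame_interval_s = 3,
                             birth_rate_per_cell_per_min = 2,
                             maturation_success_prob = 0.5,
                             marker_onset_frame = 4L,
                             biphasic_peak_frames = c(3L, 10L),
                             failure_lifetime_frames = 8L,
                             n_initial_vesicles = 0L,
                             motion_sigma_px = 1) {
  stopifnot(inherits(scene, "scene_params"))
  if (n_frames < 2) stop("n_frames must be >= 2", call. = FALSE)
  if (frame_interval_s <= 0) stop("frame_interval_s must be > 0", call. = FALSE)
  if (maturation_success_prob < 0 || maturation_success_prob > 1)
    stop("maturation_success_prob must be in [0, 1]", call. = FALSE)
  if (birth_rate_per_cell_per_min < 0)
    stop("birth_rate_per_cell_per_min must be >= 0", call. = FALSE)
  structure(c(unclass(scene),
              list(n_frames = as.integer(n_frames),
                   frame_interval_s = frame_interval_s,
                   birth_rate_per_cell_per_min = birth_rate_per_cell_per_min,
                   maturation_success_prob = maturation_success_prob,
                   marker_onset_frame = as.integer(marker_onset_frame),
                   biphasic_peak_frames = as.integer(biphasic_peak_frames),
                   failure_lifetime_frames = as.integer(failure_lifetime_frames),
                   n_initial_vesicles = as.integer(n_initial_vesicles),
                   motion_sigma_px = motion_sigma_px)),
            class = c("timelapse_params", "scene_params"))
}

# ---- RNG handling ----------------------------------------------------------

# Run code under a local RNG seeded with `seed`, restoring the caller's
# RNG state afterwards, so renders are reproducible without clobbering the
# session stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

# ---- low-level raster helpers (0-based centers, rendered on 1-based grids) --

# squared distance of every pixel center in a window to a point
window_around <- function(shape, center, reach) {
  r0 <- max(1L, floor(center[1] + 1 - reach)); r1 <- min(shape[1], ceiling(center[1] + 1 + reach))
  c0 <- max(1L, floor(center[2] + 1 - reach)); c1 <- min(shape[2], ceiling(center[2] + 1 + reach))
  list(rows = r0:r1, cols = c0:c1)
}

# add a Gaussian-cross-section annulus: amp * exp(-(d - radius)^2 / (2 s^2))
add_annulus <- function(img, center, radius, sigma, amp) {
  w <- window_around(dim(img), center, radius + 4 * sigma)
  d <- sqrt(outer((w$rows - 1 - center[1])^2, (w$cols - 1 - center[2])^2, "+"))
  img[w$rows, w$cols] <- img[w$rows, w$cols] + amp * exp(-(d - radius)^2 / (2 * sigma^2))
  img
}

# add a Gaussian spot
add_spot <- function(img, center, sigma, amp) {
  w <- window_around(dim(img), center, 4 * sigma)
  d2 <- outer((w$rows - 1 - center[1])^2, (w$cols - 1 - center[2])^2, "+")
  img[w$rows, w$cols] <- img[w$rows, w$cols] + amp * exp(-d2 / (2 * sigma^2))
  img
}

# add a line segment with Gaussian cross-section between p and q (0-based)
add_segment <- function(img, p, q, sigma, amp) {
  lo <- pmin(p, q); hi <- pmax(p, q)
  reach <- 4 * sigma
  r0 <- max(1L, floor(lo[1] + 1 - reach)); r1 <- min(dim(img)[1], ceiling(hi[1] + 1 + reach))
  c0 <- max(1L, floor(lo[2] + 1 - reach)); c1 <- min(dim(img)[2], ceiling(hi[2] + 1 + reach))
  rows <- r0:r1; cols <- c0:c1
  rr <- matrix(rows - 1, length(rows), length(cols))
  cc <- matrix(cols - 1, length(rows), length(cols), byrow = TRUE)
  v <- q - p; L2 <- sum(v^2)
  t <- if (L2 == 0) matrix(0, nrow(rr), ncol(rr)) else
    pmin(1, pmax(0, ((rr - p[1]) * v[1] + (cc - p[2]) * v[2]) / L2))
  d2 <- (rr - (p[1] + t * v[1]))^2 + (cc - (p[2] + t * v[2]))^2
  img[rows, cols] <- img[rows, cols] + amp * exp(-d2 / (2 * sigma^2))
  img
}

# hard disc mask: pixel centers within radius of center (0-based)
disc_mask_idx <- function(shape, center, radius) {
  w <- window_around(shape, center, radius + 1)
  d2 <- outer((w$rows - 1 - center[1])^2, (w$cols - 1 - center[2])^2, "+")
  sel <- which(d2 <= radius^2, arr.ind = TRUE)
  cbind(w$rows[sel[, 1]], w$cols[sel[, 2]])
}

# pixels along a segment at ~1 px spacing (unique, rounded) — skeleton truth
segment_pixels <- function(p, q) {
  len <- sqrt(sum((q - p)^2))
  n <- max(2L, ceiling(len) + 1L)
  t <- seq(0, 1, length.out = n)
  px <- unique(round(cbind(p[1] + t * (q[1] - p[1]), p[2] + t * (q[2] - p[2]))))
  px
}

sample_range <- function(r) {
  if (length(r) == 1) return(r)
  if (all(r == round(r)) && is.integer(r)) return(sample(r[1]:r[2], 1))
  runif(1, r[1], r[2])
}
sample_count <- function(r) {
  if (length(r) == 1) return(as.integer(r))
  as.integer(sample(seq(r[1], r[2]), 1))
}

# ---- cell / structure placement -------------------------------------------

place_cells <- function(p) {
  gr <- ceiling(sqrt(p$n_cells))
  gc <- ceiling(p$n_cells / gr)
  cell_rows <- p$image_shape_px[1] / gr
  cell_cols <- p$image_shape_px[2] / gc
  radius <- floor(min(cell_rows, cell_cols) / 2) - 4
  centers <- matrix(0, p$n_cells, 2)
  k <- 1
  for (i in seq_len(gr)) for (j in seq_len(gc)) {
    if (k > p$n_cells) break
    base <- c((i - 0.5) * cell_rows, (j - 0.5) * cell_cols)
    jit <- runif(2, -2, 2)
    centers[k, ] <- base + jit
    k <- k + 1
  }
  list(centers = centers, radius = radius)
}

# rejection-sample non-overlapping discs inside a cell
place_discs <- function(cell_center, cell_radius, radii, margin, max_try = 400) {
  n <- length(radii)
  centers <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (t in seq_len(max_try)) {
      ang <- runif(1, 0, 2 * pi)
      rad <- sqrt(runif(1)) * max(0, cell_radius - radii[i] - margin)
      cand <- cell_center + rad * c(cos(ang), sin(ang))
      if (i == 1 || all(sqrt(rowSums((centers[seq_len(i - 1), , drop = FALSE] -
          matrix(cand, i - 1, 2, byrow = TRUE))^2)) >
          radii[seq_len(i - 1)] + radii[i] + margin)) {
        centers[i, ] <- cand; ok <- TRUE; break
      }
    }
    if (!ok) stop("infeasible packing: could not place structure ", i,
                  " after ", max_try, " retries", call. = FALSE)
  }
  centers
}

# ---- static scene ----------------------------------------------------------

#' Render a synthetic multi-channel scene with ground truth
#'
#' Renders one static field per \code{\link{scene_params}}: the five
#' channels listed under \code{scene_channel_names}, Poisson/Gaussian noise
#' applied last. The returned ground truth records every rendered structure
#' (cells, vesicles with diameters and lumen masks, tubules with skeletons
#' and brightness flags, organelles with exact lumen dextran sums) plus the
#' noise-free channel array, and is the oracle all tests compare against.
#'
#' @param params A \code{scene_params}.
#' @return List with elements \code{stack} (an \code{\link{image_stack}},
#'   single plane) and \code{truth} (class \code{scene_truth}).
#' @export
render_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  with_seed(params$seed, render_scene_impl(params))
}

render_scene_impl <- function(p) {
  shape <- p$image_shape_px
  chans <- lapply(seq_along(scene_channel_names), function(i)
    matrix(0, shape[1], shape[2]))
  names(chans) <- scene_channel_names
  cell_layout <- place_cells(p)
  cell_masks <- matrix(0L, shape[1], shape[2])
  ves_label <- matrix(0L, shape[1], shape[2])
  org_label <- matrix(0L, shape[1], shape[2])
  ves_rec <- list(); tub_rec <- list(); org_rec <- list()
  ves_lumen <- list()
  ves_id <- 0L; tub_id <- 0L

  max_tub <- max(p$tubule_length_px_range)
  for (ci in seq_len(p$n_cells)) {
    cc <- cell_layout$centers[ci, ]; cr <- cell_layout$radius
    idx <- disc_mask_idx(shape, cc, cr)
    cell_masks[idx] <- ci
    for (ch in c("membrane", "marker2", "organelle", "dextran"))
      chans[[ch]][idx] <- chans[[ch]][idx] + p$cytoplasm_level
    chans$pm <- add_annulus(chans$pm, cc, cr, p$membrane_thickness_px,
                            p$membrane_intensity)
    # vesicles
    nv <- sample_count(p$n_vesicles_per_cell)
    if (nv > 0) {
      dia_um <- runif(nv, p$vesicle_diameter_um_range[1],
                      p$vesicle_diameter_um_range[2])
      radii_px <- dia_um * 1000 / p$pixel_size_nm / 2
      vc <- place_discs(cc, cr, radii_px + max_tub, margin = 3)
      for (vi in seq_len(nv)) {
        ves_id <- ves_id + 1L
        r <- radii_px[vi]
        chans$membrane <- add_annulus(chans$membrane, vc[vi, ], r,
                                      p$membrane_thickness_px,
                                      p$membrane_intensity)
        lum <- disc_mask_idx(shape, vc[vi, ],
                             max(1, r - 2 * p$membrane_thickness_px))
        chans$dextran[lum] <- chans$dextran[lum] + p$dextran_lumen_level
        ring <- disc_mask_idx(shape, vc[vi, ], r + 2 * p$membrane_thickness_px)
        ves_label[ring] <- ves_id
        ves_lumen[[ves_id]] <- lum
        # tubules rooted on the ring, radially outward with jittered angle
        nt <- sample_count(p$n_tubules_per_vesicle)
        angles <- if (nt > 0) (runif(1, 0, 2 * pi) +
                               seq(0, 2 * pi, length.out = nt + 1)[seq_len(nt)] +
                               runif(nt, -0.2, 0.2)) else numeric()
        tubs <- list()
        for (ti in seq_len(nt)) {
          tub_id <- tub_id + 1L
          len <- runif(1, p$tubule_length_px_range[1], p$tubule_length_px_range[2])
          u <- c(cos(angles[ti]), sin(angles[ti]))
          root <- vc[vi, ] + r * u
          tip <- root + len * u
          bright <- runif(1) < p$bright_tubule_prob
          chans$membrane <- add_segment(chans$membrane, root, tip,
                                        p$membrane_thickness_px,
                                        p$membrane_intensity)
          chans$membrane <- add_spot(chans$membrane, root,
                                     p$membrane_thickness_px,
                                     p$nucleation_spot_fold * p$membrane_intensity)
          fold <- if (bright) p$tubule_intensity_fold else p$dim_tubule_fold
          chans$marker2 <- add_segment(chans$marker2, root, tip,
                                       p$membrane_thickness_px,
                                       (fold - 1) * p$cytoplasm_level)
          tubs[[ti]] <- list(tubule_id = tub_id, vesicle_id = ves_id,
                             cell_id = ci, frame = 1L,
                             root_row = root[1], root_col = root[2],
                             tip_row = tip[1], tip_col = tip[2],
                             length_px = len, is_bright = bright)
        }
        tub_rec <- c(tub_rec, tubs)
        ves_rec[[ves_id]] <- list(id = ves_id, cell_id = ci,
                                  center_row = vc[vi, 1], center_col = vc[vi, 2],
                                  radius_px = r, diameter_um = dia_um[vi],
                                  n_tubules = nt)
      }
    }
    # organelles: puncta inside the cell, off the vesicles
    n_org_cell <- p$n_organelles %/% p$n_cells +
      (ci <= p$n_organelles %% p$n_cells)
    if (n_org_cell > 0) {
      org_r <- runif(n_org_cell, p$organelle_diameter_px_range[1] / 2,
                     p$organelle_diameter_px_range[2] / 2)
      oc <- tryCatch(place_organelles(cc, cr, org_r, ves_rec, max_tub),
                     error = function(e) stop(e))
      for (oi in seq_len(n_org_cell)) {
        oid <- max(org_label) + 1L
        om <- disc_mask_idx(shape, oc[oi, ], org_r[oi])
        om <- om[cell_masks[om] == ci & org_label[om] == 0L, , drop = FALSE]
        if (nrow(om) == 0) next
        org_label[om] <- oid
        chans$organelle[om] <- chans$organelle[om] + p$organelle_intensity
        chans$dextran[om] <- chans$dextran[om] + p$dextran_lumen_level
        org_rec[[oid]] <- list(id = oid, cell_id = ci,
                               center_row = oc[oi, 1], center_col = oc[oi, 2],
                               area_px = nrow(om),
                               lumen_dextran_sum = nrow(om) * p$dextran_lumen_level)
      }
    }
  }

  noise_free <- array(0, dim = c(1, length(chans), shape[1], shape[2]))
  for (i in seq_along(chans)) noise_free[1, i, , ] <- chans[[i]]
  noisy <- noise_free
  if (p$noise$poisson_scale > 0 || p$noise$read_sigma > 0)
    for (i in seq_along(chans))
      noisy[1, i, , ] <- add_noise_impl(noise_free[1, i, , ],
                                        p$noise$poisson_scale,
                                        p$noise$read_sigma)
  stack <- image_stack(noisy, axis_kind = "time",
                       pixel_size_nm = p$pixel_size_nm,
                       frame_interval_s = 3,
                       channel_names = scene_channel_names)
  truth <- structure(list(
    params = p,
    cell_masks = cell_masks,
    cell_centers = cell_layout$centers,
    cell_radius_px = cell_layout$radius,
    vesicle_records = rbind_records(ves_rec),
    tubule_records = rbind_records(tub_rec),
    organelle_records = rbind_records(org_rec),
    vesicle_label = ves_label,
    vesicle_lumens = ves_lumen,
    organelle_label = org_label,
    noise_free_channels = noise_free), class = "scene_truth")
  list(stack = stack, truth = truth)
}

place_organelles <- function(cc, cr, org_r, ves_rec, max_tub) {
  n <- length(org_r)
  centers <- matrix(NA_real_, n, 2)
  vr <- if (length(ves_rec))
    do.call(rbind, lapply(ves_rec, function(v)
      c(v$center_row, v$center_col, v$radius_px))) else NULL
  for (i in seq_len(n)) {
    ok <- FALSE
    for (t in 1:400) {
      ang <- runif(1, 0, 2 * pi)
      rad <- sqrt(runif(1)) * max(0, cr - org_r[i] - 3)
      cand <- cc + rad * c(cos(ang), sin(ang))
      clear_ves <- is.null(vr) ||
        all(sqrt((vr[, 1] - cand[1])^2 + (vr[, 2] - cand[2])^2) >
            vr[, 3] + max_tub + org_r[i] + 3)
      clear_org <- i == 1 ||
        all(sqrt(rowSums((centers[seq_len(i - 1), , drop = FALSE] -
            matrix(cand, i - 1, 2, byrow = TRUE))^2)) >
            org_r[seq_len(i - 1)] + org_r[i] + 2)
      if (clear_ves && clear_org) { centers[i, ] <- cand; ok <- TRUE; break }
    }
    if (!ok) stop("infeasible packing: could not place organelle ", i,
                  call. = FALSE)
  }
  centers
}

rbind_records <- function(recs) {
  recs <- recs[!vapply(recs, is.null, TRUE)]
  if (!length(recs)) return(NULL)
  do.call(rbind, lapply(recs, function(r) as.data.frame(r)))
}

# ---- noise -----------------------------------------------------------------

add_noise_impl <- function(img, poisson_scale, read_sigma) {
  out <- img
  if (poisson_scale > 0)
    out <- matrix(rpois(length(img), img * poisson_scale) / poisson_scale,
                  nrow(img), ncol(img))
  if (read_sigma > 0)
    out <- out + matrix(rnorm(length(img), 0, read_sigma), nrow(img), ncol(img))
  pmax(out, 0)
}

#' Apply Poisson shot noise and Gaussian read noise
#'
#' Each pixel is replaced by
#' \code{Poisson(pixel * poisson_scale) / poisson_scale +
#' Normal(0, read_sigma)}, clamped at zero. \code{poisson_scale} plays the
#' role of a photon-per-intensity-unit gain: larger values mean less shot
#' noise; zero disables the Poisson component.
#'
#' @param image Non-negative numeric matrix.
#' @param poisson_scale Photon gain (>= 0).
#' @param read_sigma Read-noise standard deviation (>= 0).
#' @param seed Integer seed; the same seed reproduces the output exactly.
#' @return Noisy matrix of the same shape.
#' @export
add_noise <- function(image, poisson_scale, read_sigma, seed) {
  if (any(!is.finite(image)) || any(image < 0))
    stop("image must be finite and non-negative", call. = FALSE)
  if (poisson_scale < 0 || read_sigma < 0)
    stop("noise parameters must be non-negative", call. = FALSE)
  with_seed(seed, add_noise_impl(image, poisson_scale, read_sigma))
}

# ---- time-lapse ------------------------------------------------------------

# biphasic membrane-marker recruitment envelope (frames since birth)
biphasic_envelope <- function(age, peaks, width1 = 1.5, width2 = 3, w2 = 0.6) {
  e <- exp(-(age - peaks[1])^2 / (2 * width1^2)) +
    w2 * exp(-(age - peaks[2])^2 / (2 * width2^2))
  e / max(exp(0) + w2 * exp(-(peaks[1] - peaks[2])^2 / (2 * width2^2)), 1)
}

#' Render a synthetic time-lapse with birth, maturation and failure
#'
#' Vesicles are born at Poisson-distributed times (rate
#' \code{birth_rate_per_cell_per_min}); with probability
#' \code{maturation_success_prob} a vesicle succeeds — it acquires the
#' maturation-marker channel (\code{marker2}) \code{marker_onset_frame}
#' frames after birth and persists to the movie end — otherwise it fails:
#' it vanishes back into the plasma membrane after
#' \code{failure_lifetime_frames} frames, never marker-positive. The
#' membrane-marker ring amplitude follows a biphasic envelope peaking at
#' \code{biphasic_peak_frames} after birth. Centroids undergo Gaussian
#' per-frame jitter.
#'
#' @param params A \code{timelapse_params}.
#' @return List with \code{stack} (time \code{\link{image_stack}}) and
#'   \code{truth} (class \code{timelapse_truth}: per-vesicle fate, birth
#'   frame, marker onset, per-frame presence and centers).
#' @export
render_timelapse <- function(params) {
  stopifnot(inherits(params, "timelapse_params"))
  with_seed(params$seed, render_timelapse_impl(params))
}

render_timelapse_impl <- function(p) {
  shape <- p$image_shape_px
  nf <- p$n_frames
  cell_layout <- place_cells(p)
  cell_masks <- matrix(0L, shape[1], shape[2])
  for (ci in seq_len(p$n_cells))
    cell_masks[disc_mask_idx(shape, cell_layout$centers[ci, ],
                             cell_layout$radius)] <- ci

  # births: Poisson per cell per frame
  rate_per_frame <- p$birth_rate_per_cell_per_min * p$frame_interval_s / 60
  births <- list()
  for (ci in seq_len(p$n_cells)) {
    for (k in seq_len(p$n_initial_vesicles %/% p$n_cells +
                      (ci <= p$n_initial_vesicles %% p$n_cells)))
      births[[length(births) + 1L]] <- list(cell = ci, frame = 1L,
                                            initial = TRUE)
    nb <- rpois(nf - 1L, rate_per_frame)
    for (f in which(nb > 0)) for (k in seq_len(nb[f]))
      births[[length(births) + 1L]] <- list(cell = ci, frame = f + 1L,
                                            initial = FALSE)
  }
  nv <- length(births)
  ves <- vector("list", nv)
  centers <- array(NA_real_, dim = c(max(nv, 1), nf, 2))
  present <- matrix(FALSE, max(nv, 1), nf)
  if (nv > 0) {
    dia_um <- runif(nv, p$vesicle_diameter_um_range[1],
                    p$vesicle_diameter_um_range[2])
    radii_px <- dia_um * 1000 / p$pixel_size_nm / 2
    for (vi in seq_len(nv)) {
      b <- births[[vi]]
      fate <- if (b$initial) "initial"
      else if (runif(1) < p$maturation_success_prob) "success" else "failure"
      last <- if (fate == "failure")
        min(nf, b$frame + p$failure_lifetime_frames - 1L) else nf
      onset <- if (fate == "success") b$frame + p$marker_onset_frame
               else NA_integer_
      ves[[vi]] <- list(id = vi, cell_id = b$cell,
                        birth_frame = b$frame,
                        present_at_start = b$initial,
                        fate = fate,
                        diameter_um = dia_um[vi], radius_px = radii_px[vi],
                        last_frame = last,
                        marker_onset_frame = onset)
    }
    # frame-major position simulation with excluded volume: vesicles are
    # solid; a birth or step that would overlap a live vesicle is retried
    # (birth) or rejected (step)
    pos_cur <- matrix(NA_real_, nv, 2)
    # excluded volume includes the membrane band so rendered rings of
    # neighbouring vesicles stay resolvable
    margin <- 4 * p$membrane_thickness_px
    clear_of_others <- function(vi, cand, active) {
      others <- setdiff(active, vi)
      others <- others[!is.na(pos_cur[others, 1])]
      if (!length(others)) return(TRUE)
      all(sqrt((pos_cur[others, 1] - cand[1])^2 +
               (pos_cur[others, 2] - cand[2])^2) >
            radii_px[others] + radii_px[vi] + margin)
    }
    for (f in seq_len(nf)) {
      active <- which(vapply(ves, function(v)
        f >= v$birth_frame && f <= v$last_frame, TRUE))
      for (vi in active) {
        b <- births[[vi]]
        cc <- cell_layout$centers[b$cell, ]; cr <- cell_layout$radius
        if (f == ves[[vi]]$birth_frame) {
          placed <- FALSE
          for (t in 1:200) {
            ang <- runif(1, 0, 2 * pi)
            rad0 <- if (b$initial) sqrt(runif(1)) * (cr - radii_px[vi] - 4)
                    else cr - radii_px[vi] - 4
            cand <- cc + rad0 * c(cos(ang), sin(ang))
            if (clear_of_others(vi, cand, active)) {
              pos_cur[vi, ] <- cand; placed <- TRUE; break
            }
          }
          if (!placed)
            stop("infeasible packing: could not place vesicle ", vi,
                 " at birth after 200 retries", call. = FALSE)
        } else {
          inward <- cc - pos_cur[vi, ]
          inward <- inward / max(sqrt(sum(inward^2)), 1)
          drift <- if (b$initial) c(0, 0) else inward * 0.5
          cand <- pos_cur[vi, ] + drift + rnorm(2, 0, p$motion_sigma_px)
          cand <- pmin(pmax(cand, radii_px[vi] + 2),
                       c(shape[1], shape[2]) - radii_px[vi] - 3)
          if (clear_of_others(vi, cand, active)) pos_cur[vi, ] <- cand
        }
        present[vi, f] <- TRUE
        centers[vi, f, ] <- pos_cur[vi, ]
      }
    }
  }

  chans <- scene_channel_names
  px <- array(0, dim = c(nf, length(chans), shape[1], shape[2]))
  noise_free <- px
  for (f in seq_len(nf)) {
    frame_ch <- lapply(chans, function(x) matrix(0, shape[1], shape[2]))
    names(frame_ch) <- chans
    for (ci in seq_len(p$n_cells)) {
      idx <- disc_mask_idx(shape, cell_layout$centers[ci, ], cell_layout$radius)
      for (ch in c("membrane", "marker2", "organelle", "dextran"))
        frame_ch[[ch]][idx] <- frame_ch[[ch]][idx] + p$cytoplasm_level
      frame_ch$pm <- add_annulus(frame_ch$pm, cell_layout$centers[ci, ],
                                 cell_layout$radius, p$membrane_thickness_px,
                                 p$membrane_intensity)
    }
    for (vi in seq_len(nv)) {
      if (!present[vi, f]) next
      v <- ves[[vi]]
      pos <- centers[vi, f, ]
      age <- f - v$birth_frame
      env <- if (v$present_at_start) 1 else
        pmax(biphasic_envelope(age, p$biphasic_peak_frames), 0.35)
      frame_ch$membrane <- add_annulus(frame_ch$membrane, pos, v$radius_px,
                                       p$membrane_thickness_px,
                                       env * p$membrane_intensity)
      lum <- disc_mask_idx(shape, pos,
                           max(1, v$radius_px - 2 * p$membrane_thickness_px))
      frame_ch$dextran[lum] <- frame_ch$dextran[lum] + p$dextran_lumen_level
      marker_on <- v$present_at_start ||
        (!is.na(v$marker_onset_frame) && f >= v$marker_onset_frame)
      if (marker_on)
        frame_ch$marker2 <- add_annulus(frame_ch$marker2, pos, v$radius_px,
                                        p$membrane_thickness_px,
                                        p$tubule_intensity_fold *
                                          p$membrane_intensity / 2)
    }
    for (i in seq_along(chans)) noise_free[f, i, , ] <- frame_ch[[chans[i]]]
  }
  px <- noise_free
  if (p$noise$poisson_scale > 0 || p$noise$read_sigma > 0)
    for (f in seq_len(nf)) for (i in seq_along(chans))
      px[f, i, , ] <- add_noise_impl(noise_free[f, i, , ],
                                     p$noise$poisson_scale, p$noise$read_sigma)
  stack <- image_stack(px, axis_kind = "time",
                       pixel_size_nm = p$pixel_size_nm,
                       frame_interval_s = p$frame_interval_s,
                       channel_names = chans)
  vr <- rbind_records(lapply(ves, function(v)
    v[c("id", "cell_id", "birth_frame", "present_at_start", "fate",
        "diameter_um", "radius_px", "last_frame", "marker_onset_frame")]))
  truth <- structure(list(params = p, cell_masks = cell_masks,
                          cell_centers = cell_layout$centers,
                          cell_radius_px = cell_layout$radius,
                          vesicle_records = vr,
                          centers = centers, present = present,
                          noise_free_channels = noise_free),
                     class = "timelapse_truth")
  list(stack = stack, truth = truth)
}

#' Write ground truth to JSON (records) plus label-map TIFFs
#'
#' @param truth A \code{scene_truth} or \code{timelapse_truth}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_ground_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  recs <- list(vesicle_records = truth$vesicle_records,
               tubule_records = truth$tubule_records,
               organelle_records = truth$organelle_records)
  jsonlite::write_json(recs[!vapply(recs, is.null, TRUE)],
                       file.path(dir, "ground_truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  lab <- list(cell_masks = truth$cell_masks,
              vesicle_label = truth$vesicle_label,
              organelle_label = truth$organelle_label)
  for (nm in names(lab)) if (!is.null(lab[[nm]]))
    tiff::writeTIFF(lab[[nm]] / 65535, file.path(dir, paste0(nm, ".tif")),
                    bits.per.sample = 16L)
  invisible(dir)
}
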