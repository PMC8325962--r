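# Detection, linking and filtering of macropinosomes over time; diameters,
# formation frequencies and maturation success rates.

#' Detect marker-positive structures in every frame
#'
#' Runs \code{\link{segment_structures}} on the marker channel of each
#' frame, fills holes (a macropinosome's limiting membrane segments as a
#' ring) and measures every channel over each filled structure. For solid
#' structures the equivalent radius is the area-equivalent circle radius,
#' \code{sqrt(area_px / pi) * pixel_size_nm}; for hollow (ring) structures
#' it is corrected to the ring centerline — the filled radius minus half
#' the ring band width — so the reported radius tracks the limiting
#' membrane rather than the outer edge of the thresholded band.
#'
#' @param stack A time \code{\link{image_stack}}.
#' @param marker_channel Channel segmented to define structures.
#' @param config An \code{\link{analysis_config}}.
#' @return Data frame of detections: \code{frame, structure_id,
#'   centroid_row, centroid_col, area_px, equivalent_radius_nm} and
#'   \code{mean_<channel>} per channel.
#' @export
detect_per_frame <- function(stack, marker_channel = "membrane",
                             config = analysis_config()) {
  stopifnot(inherits(stack, "image_stack"))
  ch <- resolve_channel(stack, marker_channel)
  d <- dim(stack$pixels)
  out <- vector("list", d[1])
  for (f in seq_len(d[1])) {
    mask <- segment_structures(stack$pixels[f, ch, , ], config)
    if (mask$n_structures == 0L) next
    bw <- mask$labels > 0L
    filled <- EBImage::imageData(
      EBImage::fillHull(EBImage::Image(bw * 1))) > 0
    labf <- prune_relabel(label_components8(filled),
                          config$min_structure_area_px)
    if (max(labf) == 0L) next
    maskf <- label_mask(labf)
    rec <- measure_structures(maskf, stack$pixels[f, , , , drop = TRUE],
                              channel_names = stack$channel_names)
    rec$frame <- f
    # ring-centerline radius: r solves r = r_fill - ring_area / (4 pi r)
    ring_area <- vapply(seq_len(maskf$n_structures), function(l)
      sum(bw[labf == l]), 1)
    r_fill <- sqrt(rec$area_px / pi)
    r <- r_fill
    hollow <- rec$area_px - ring_area >= 4      # a resolvable lumen hole
    for (it in 1:6)
      r[hollow] <- r_fill[hollow] - ring_area[hollow] / (4 * pi * r[hollow])
    rec$equivalent_radius_nm <- r * stack$pixel_size_nm
    out[[f]] <- rec
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out))
    return(data.frame(frame = integer(), structure_id = integer(),
                      centroid_row = numeric(), centroid_col = numeric(),
                      area_px = integer(), equivalent_radius_nm = numeric()))
  do.call(rbind, out)
}

#' Link per-frame detections into tracks
#'
#' Greedy mutual-nearest-neighbour linking: at each frame, the closest
#' (track, detection) pairs are joined in order of centroid distance as
#' long as the displacement does not exceed \code{max_displacement_nm}
#' (scaled by the bridged gap). Tracks not matched for more than
#' \code{max_gap} frames are closed; unmatched detections open new tracks,
#' so every detection belongs to exactly one track.
#'
#' @param detections Data frame from \code{\link{detect_per_frame}}.
#' @param pixel_size_nm Lateral calibration for displacement limits.
#' @param config An \code{\link{analysis_config}} (defaults
#'   \code{max_displacement_nm = 1600}, \code{max_gap = 2}).
#' @return List of tracks, each \code{list(track_id, detections,
#'   born_at_frame, present_at_start, fate = "unclassified")}, detections
#'   ordered by frame.
#' @export
link_tracks <- function(detections, pixel_size_nm = 80,
                        config = analysis_config()) {
  if (!nrow(detections)) return(list())
  detections <- detections[order(detections$frame), , drop = FALSE]
  frames <- sort(unique(detections$frame))
  max_disp_px <- config$max_displacement_nm / pixel_size_nm
  tracks <- list()           # each: list(rows = row indices, last_frame, pos)
  open <- integer()          # indices into tracks that may still be extended
  for (f in frames) {
    det_i <- which(detections$frame == f)
    pos <- cbind(detections$centroid_row[det_i],
                 detections$centroid_col[det_i])
    # drop tracks whose gap exceeded max_gap
    if (length(open))
      open <- open[f - vapply(tracks[open], `[[`, 1, "last_frame") <=
                     config$max_gap + 1L]
    if (length(open) && length(det_i)) {
      tpos <- do.call(rbind, lapply(tracks[open], `[[`, "pos"))
      gap <- f - vapply(tracks[open], `[[`, 1, "last_frame")
      dmat <- sqrt(outer(tpos[, 1], pos[, 1], "-")^2 +
                   outer(tpos[, 2], pos[, 2], "-")^2)
      lim <- matrix(gap * max_disp_px, nrow(dmat), ncol(dmat))
      dmat[dmat > lim] <- Inf
      # greedy: repeatedly take the globally closest admissible pair
      while (any(is.finite(dmat))) {
        k <- arrayInd(which.min(dmat), dim(dmat))
        ti <- open[k[1]]; di <- det_i[k[2]]
        tracks[[ti]]$rows <- c(tracks[[ti]]$rows, di)
        tracks[[ti]]$last_frame <- f
        tracks[[ti]]$pos <- c(detections$centroid_row[di],
                              detections$centroid_col[di])
        dmat[k[1], ] <- Inf
        dmat[, k[2]] <- Inf
        det_i[k[2]] <- NA_integer_
      }
      det_i <- det_i[!is.na(det_i)]
    }
    for (di in det_i) {
      tracks[[length(tracks) + 1L]] <-
        list(rows = di, last_frame = f,
             pos = c(detections$centroid_row[di],
                     detections$centroid_col[di]))
      open <- c(open, length(tracks))
    }
    # matched tracks stay open
    open <- unique(c(open, which(vapply(tracks, `[[`, 1, "last_frame") == f)))
  }
  first_frame <- min(frames)
  lapply(seq_along(tracks), function(i) {
    det <- detections[tracks[[i]]$rows, , drop = FALSE]
    det <- det[order(det$frame), , drop = FALSE]
    list(track_id = sprintf("track%03d", i), detections = det,
         born_at_frame = det$frame[1],
         present_at_start = det$frame[1] == first_frame,
         fate = "unclassified")
  })
}

#' Keep only newly formed, full-sized tracks
#'
#' Applies the two exclusion rules for newly formed macropinosomes: tracks
#' whose median equivalent radius is below \code{min_track_radius_nm}
#' (default 400 nm), and tracks that existed from the beginning of the
#' time-lapse, are removed. Pure predicate: output is an order-preserving
#' subset of the input.
#'
#' @param tracks List of tracks from \code{\link{link_tracks}}.
#' @param config An \code{\link{analysis_config}}.
#' @return Filtered list of tracks.
#' @export
filter_new_tracks <- function(tracks, config = analysis_config()) {
  keep <- vapply(tracks, function(tr) {
    median(tr$detections$equivalent_radius_nm) >= config$min_track_radius_nm &&
      !tr$present_at_start
  }, TRUE)
  tracks[keep]
}

#' Diameters and formation frequency of accepted tracks
#'
#' Per-track diameter is twice the median equivalent radius, in um; the
#' formation frequency is \code{count / (n_cells * duration_min)} events
#' per cell per minute.
#'
#' @param tracks Filtered list of tracks.
#' @param duration_min Movie duration in minutes.
#' @param n_cells Number of cells in the field.
#' @return List with \code{diameters_um} (one per track) and
#'   \code{frequency_per_cell_per_min}.
#' @export
track_metrics <- function(tracks, duration_min, n_cells) {
  if (duration_min <= 0) stop("duration must be > 0", call. = FALSE)
  if (n_cells < 1) stop("n_cells must be >= 1", call. = FALSE)
  dia <- vapply(tracks, function(tr)
    2 * median(tr$detections$equivalent_radius_nm) / 1000, 1)
  list(diameters_um = dia,
       frequency_per_cell_per_min = length(tracks) / (n_cells * duration_min))
}

#' Classify the maturation fate of a track
#'
#' A vesicle is \code{"success"} when its maturation-marker mean (inside
#' the vesicle) exceeds \code{success_fold} times the cytoplasmic
#' background for at least \code{success_min_frames} consecutive frames
#' before the track ends — acquisition of PtdIns3P marking the transition
#' to an early macropinosome. It is \code{"failure"} when the track
#' terminates (re-merging with the plasma membrane) before the movie ends
#' without marker acquisition, and \code{"censored"} when the movie ends
#' first. The stack must carry a plasma-membrane channel, since formation
#' is tracked off the plasma membrane.
#'
#' @param track One track (detections must include
#'   \code{mean_<marker_channel>}).
#' @param stack The time \code{\link{image_stack}} the track came from.
#' @param background Cytoplasmic background of the marker channel (> 0).
#' @param config An \code{\link{analysis_config}}.
#' @param marker_channel Maturation marker channel name.
#' @param pm_channel Plasma-membrane channel name.
#' @return \code{"success"}, \code{"failure"} or \code{"censored"}.
#' @export
classify_maturation <- function(track, stack, background,
                                config = analysis_config(),
                                marker_channel = "marker2",
                                pm_channel = "pm") {
  stopifnot(inherits(stack, "image_stack"))
  if (!pm_channel %in% stack$channel_names)
    stop("plasma-membrane channel '", pm_channel,
         "' missing from the stack", call. = FALSE)
  if (background <= 0) stop("background must be > 0", call. = FALSE)
  col <- paste0("mean_", marker_channel)
  if (!col %in% names(track$detections))
    stop("track detections lack ", col, call. = FALSE)
  marker <- track$detections[[col]]
  pos <- marker >= config$success_fold * background
  run <- rle(pos)
  if (any(run$values & run$lengths >= config$success_min_frames))
    return("success")
  last <- max(track$detections$frame)
  if (last < n_planes(stack) - config$max_gap) "failure" else "censored"
}

#' Maturation success rate over a set of tracks
#'
#' Fraction of non-censored tracks classified \code{"success"}; censored
#' tracks (fate unknown at movie end) are excluded from the denominator.
#'
#' @param fates Character vector of fates from
#'   \code{\link{classify_maturation}}.
#' @return List with \code{n_success, n_failure, n_censored,
#'   success_rate}.
#' @export
maturation_success_rate <- function(fates) {
  ns <- sum(fates == "success"); nf <- sum(fates == "failure")
  list(n_success = ns, n_failure = nf,
       n_censored = sum(fates == "censored"),
       success_rate = if (ns + nf > 0) ns / (ns + nf) else NA_real_)
}

#' Export tracks as CSV
#'
#' Columns: \code{track_id, frame, row, col, radius_nm, fate}.
#'
#' @param tracks List of tracks.
#' @param path Output CSV path.
#' @export
write_tracks <- function(tracks, path) {
  rows <- do.call(rbind, lapply(tracks, function(tr)
    data.frame(track_id = tr$track_id, frame = tr$detections$frame,
               row = tr$detections$centroid_row,
               col = tr$detections$centroid_col,
               radius_nm = tr$detections$equivalent_radius_nm,
               fate = tr$fate)))
  if (is.null(rows))
    rows <- data.frame(track_id = character(), frame = integer(),
                       row = numeric(), col = numeric(),
                       radius_nm = numeric(), fate = character())
  write.csv(rows, path, row.names = FALSE, na = "NA")
  invisible(path)
}
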