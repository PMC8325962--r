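#' @import EBImage
#' @importFrom stats sd qt rpois rnorm rbinom runif cor median complete.cases
#' @importFrom utils read.csv write.csv head tail
NULL

# Coordinate convention used throughout the package:
#   0-based (row, col), pixel centers at integer coordinates.
#   Row 0 is the top image row; R's 1-based matrix index is (row + 1, col + 1).

#' Multi-channel image stack with physical calibration
#'
#' Container for a 4-D fluorescence image stack indexed
#' \code{[plane, channel, row, col]}, where the plane axis is either time
#' (a time-lapse) or z (a z-stack). Physical calibration (nm per pixel,
#' seconds per frame or nm per z-step) travels with the pixel data so that
#' all downstream quantities can be reported in physical units.
#'
#' Intensities are stored as doubles; they must be finite and non-negative.
#' Detector saturation is not modeled.
#'
#' @param pixels 4-D numeric array, dimensions
#'   \code{(planes, channels, rows, cols)}. A 2-D matrix or 3-D array
#'   (single plane and/or single channel) is promoted.
#' @param axis_kind \code{"time"} or \code{"z"}: what the first axis means.
#' @param pixel_size_nm Lateral calibration, nanometres per pixel (> 0).
#' @param frame_interval_s Seconds between frames (time stacks).
#' @param z_step_nm Nanometres between planes (z stacks).
#' @param channel_names Character vector naming the channels; defaults to
#'   \code{"ch1"}, \code{"ch2"}, ...
#' @return An object of class \code{image_stack}.
#' @export
image_stack <- function(pixels, axis_kind = c("time", "z"),
                        pixel_size_nm = 80,
                        frame_interval_s = NULL, z_step_nm = NULL,
                        channel_names = NULL) {
  axis_kind <- match.arg(axis_kind)
  if (is.matrix(pixels)) dim(pixels) <- c(1L, 1L, dim(pixels))
  if (length(dim(pixels)) == 3L) dim(pixels) <- c(1L, dim(pixels))
  if (length(dim(pixels)) != 4L)
    stop("pixels must be a 2-D, 3-D or 4-D array", call. = FALSE)
  storage.mode(pixels) <- "double"
  if (any(!is.finite(pixels)))
    stop("pixel intensities must be finite", call. = FALSE)
  if (any(pixels < 0))
    stop("pixel intensities must be non-negative", call. = FALSE)
  if (!is.numeric(pixel_size_nm) || pixel_size_nm <= 0)
    stop("pixel_size_nm must be a positive number", call. = FALSE)
  nc <- dim(pixels)[2]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nc))
  if (length(channel_names) != nc)
    stop("channel_names length must equal the channel dimension (", nc, ")",
         call. = FALSE)
  if (axis_kind == "time") {
    if (is.null(frame_interval_s)) frame_interval_s <- 3
    if (frame_interval_s <= 0) stop("frame_interval_s must be > 0", call. = FALSE)
    z_step_nm <- NULL
  } else {
    if (is.null(z_step_nm)) z_step_nm <- 250
    if (z_step_nm <= 0) stop("z_step_nm must be > 0", call. = FALSE)
    frame_interval_s <- NULL
  }
  structure(list(pixels = pixels, axis_kind = axis_kind,
                 pixel_size_nm = pixel_size_nm,
                 frame_interval_s = frame_interval_s,
                 z_step_nm = z_step_nm,
                 channel_names = as.character(channel_names)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_stack> %d %s plane(s) x %d channel(s), %d x %d px\n",
              d[1], x$axis_kind, d[2], d[3], d[4]))
  cat(sprintf("  pixel size: %g nm/px", x$pixel_size_nm))
  if (x$axis_kind == "time")
    cat(sprintf(", frame interval: %g s", x$frame_interval_s))
  else
    cat(sprintf(", z step: %g nm", x$z_step_nm))
  cat("\n  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$pixels)

#' Number of planes (frames or z-slices) in a stack
#' @param stack An \code{image_stack}.
#' @return Integer plane count.
#' @export
n_planes <- function(stack) dim(stack$pixels)[1]

#' Extract one channel of one plane as a matrix
#'
#' @param stack An \code{image_stack}.
#' @param plane 1-based plane index (frame or z-slice).
#' @param channel Channel name or 1-based index.
#' @return Numeric matrix (rows x cols).
#' @export
get_plane <- function(stack, plane = 1L, channel = 1L) {
  stopifnot(inherits(stack, "image_stack"))
  ch <- resolve_channel(stack, channel)
  if (plane < 1 || plane > dim(stack$pixels)[1])
    stop("plane index out of range", call. = FALSE)
  stack$pixels[plane, ch, , ]
}

resolve_channel <- function(stack, channel) {
  if (is.character(channel)) {
    ch <- match(channel, stack$channel_names)
    if (is.na(ch)) stop("unknown channel: ", channel, call. = FALSE)
    return(ch)
  }
  ch <- as.integer(channel)
  if (ch < 1 || ch > dim(stack$pixels)[2])
    stop("channel index out of range", call. = FALSE)
  ch
}

#' Analysis configuration
#'
#' All tunable parameters of the quantification pipeline in one validated
#' list. Defaults correspond to the acquisition and analysis settings the
#' pipeline was designed around: 80 nm/px sampling, "at least five pixels"
#' structure segmentation, tubules longer than six pixels, a 1.5-fold
#' positivity threshold over cytoplasmic background estimated in a
#' 100 x 100 px square, three-pixel-wide line profiles with a 15-px
#' background-exclusion window, a ten-pixel circular membrane ROI, trace
#' alignment at 15 s, macropinosomes over 1 um in diameter, and a 400 nm
#' minimum track radius.
#'
#' @param min_structure_area_px Minimum segmented-structure area (px).
#' @param tubule_min_length_px Tubules must exceed this skeleton length (px).
#' @param positive_fold_threshold Positivity threshold as a fold of
#'   cytoplasmic background (inclusive).
#' @param background_square_px Side of the square used to estimate
#'   cytoplasmic background (px).
#' @param profile_exclusion_window_px Odd width of the window centred on the
#'   tubule position that is excluded from the profile background.
#' @param profile_width_px Width of line/contour profiles (px).
#' @param min_macropinosome_diameter_um Eligibility diameter for the
#'   circumference CV statistic (um).
#' @param membrane_roi_diameter_px Diameter of the moving circular membrane
#'   ROI (px).
#' @param trace_align_time_s Time point the reference-channel peak is aligned
#'   to (s).
#' @param min_track_radius_nm Tracks with median equivalent radius below this
#'   are excluded (nm).
#' @param threshold_method \code{"otsu"} or \code{"absolute"}.
#' @param absolute_threshold Threshold used when
#'   \code{threshold_method = "absolute"}.
#' @param max_displacement_nm Maximum frame-to-frame centroid displacement for
#'   track linking (nm).
#' @param max_gap Maximum number of missed frames a track may bridge.
#' @param success_fold Marker fold over cytoplasm required for maturation
#'   success.
#' @param success_min_frames Consecutive marker-positive frames required for
#'   maturation success.
#' @param cv_sd_denominator \code{"n-1"} (sample SD, default) or \code{"n"}.
#' @param random_seed Optional integer seed recorded with the config.
#' @return An object of class \code{analysis_config}.
#' @export
analysis_config <- function(min_structure_area_px = 5L,
                            tubule_min_length_px = 6L,
                            positive_fold_threshold = 1.5,
                            background_square_px = 100L,
                            profile_exclusion_window_px = 15L,
                            profile_width_px = 3L,
                            min_macropinosome_diameter_um = 1.0,
                            membrane_roi_diameter_px = 10L,
                            trace_align_time_s = 15,
                            min_track_radius_nm = 400,
                            threshold_method = c("otsu", "absolute"),
                            absolute_threshold = NULL,
                            max_displacement_nm = 1600,
                            max_gap = 2L,
                            success_fold = 1.5,
                            success_min_frames = 2L,
                            cv_sd_denominator = c("n-1", "n"),
                            random_seed = NULL) {
  threshold_method <- match.arg(threshold_method)
  cv_sd_denominator <- match.arg(cv_sd_denominator)
  cfg <- list(min_structure_area_px = as.integer(min_structure_area_px),
              tubule_min_length_px = as.integer(tubule_min_length_px),
              positive_fold_threshold = positive_fold_threshold,
              background_square_px = as.integer(background_square_px),
              profile_exclusion_window_px = as.integer(profile_exclusion_window_px),
              profile_width_px = as.integer(profile_width_px),
              min_macropinosome_diameter_um = min_macropinosome_diameter_um,
              membrane_roi_diameter_px = as.integer(membrane_roi_diameter_px),
              trace_align_time_s = trace_align_time_s,
              min_track_radius_nm = min_track_radius_nm,
              threshold_method = threshold_method,
              absolute_threshold = absolute_threshold,
              max_displacement_nm = max_displacement_nm,
              max_gap = as.integer(max_gap),
              success_fold = success_fold,
              success_min_frames = as.integer(success_min_frames),
              cv_sd_denominator = cv_sd_denominator,
              random_seed = if (is.null(random_seed)) NULL else as.integer(random_seed))
  sizes <- c("min_structure_area_px", "tubule_min_length_px",
             "background_square_px", "profile_exclusion_window_px",
             "profile_width_px", "membrane_roi_diameter_px",
             "min_macropinosome_diameter_um", "min_track_radius_nm",
             "max_displacement_nm", "trace_align_time_s")
  for (nm in sizes)
    if (cfg[[nm]] <= 0) stop(nm, " must be positive", call. = FALSE)
  if (cfg$positive_fold_threshold <= 0)
    stop("positive_fold_threshold must be > 0", call. = FALSE)
  if (cfg$profile_exclusion_window_px %% 2L == 0L)
    stop("profile_exclusion_window_px must be odd", call. = FALSE)
  if (threshold_method == "absolute" && is.null(absolute_threshold))
    stop("absolute_threshold required when threshold_method = 'absolute'",
         call. = FALSE)
  structure(cfg, class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Keys mirror the arguments of \code{\link{analysis_config}}; unknown keys
#' are an error so that typos do not silently fall back to defaults.
#'
#' @param path Path to a YAML file.
#' @return An \code{analysis_config}.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(analysis_config, vals)
}

#' Write an analysis configuration to YAML
#' @param config An \code{analysis_config}.
#' @param path Output path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  yaml::write_yaml(config[!vapply(config, is.null, logical(1))], path)
  invisible(path)
}

# ---- TIFF image I/O --------------------------------------------------------
# Pages are written plane-major: page index = (plane - 1) * n_channels +
# channel. A sidecar JSON (<path>.json) records axis kind, calibration,
# channel names and the intensity scale used to map data into TIFF range.

#' Write an image stack as a multi-page TIFF with a calibration sidecar
#'
#' Integer-valued stacks with a maximum below 2^16 are written as 16-bit
#' pages and round-trip bit-exactly; other data are written as 32-bit float
#' scaled into [0, 1], with the scale recorded in the sidecar JSON
#' (\code{<path>.json}) alongside axis kind, calibration and channel names.
#' Page order is plane-major (all channels of plane 1, then plane 2, ...).
#'
#' @param stack An \code{image_stack}.
#' @param path Output TIFF path; the sidecar is written to \code{<path>.json}.
#' @return \code{path}, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  px <- stack$pixels
  d <- dim(px)
  integerish <- all(px == round(px)) && max(px) < 65536
  if (integerish) {
    scale <- 65535
    bits <- 16L
  } else {
    scale <- max(px, 1)
    bits <- 32L
  }
  pages <- vector("list", d[1] * d[2])
  k <- 1L
  for (p in seq_len(d[1])) for (ch in seq_len(d[2])) {
    pages[[k]] <- px[p, ch, , ] / scale
    k <- k + 1L
  }
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = bits), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("failed to write TIFF to ", path, call. = FALSE)
  sidecar <- list(axis_kind = stack$axis_kind,
                  n_planes = d[1], n_channels = d[2],
                  pixel_size_nm = stack$pixel_size_nm,
                  frame_interval_s = stack$frame_interval_s,
                  z_step_nm = stack$z_step_nm,
                  channel_names = as.list(stack$channel_names),
                  intensity_scale = scale,
                  bits_per_sample = bits,
                  page_order = "plane_major")
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a multi-page TIFF image stack
#'
#' Reads a stack written by \code{\link{write_image_stack}} (sidecar JSON
#' found automatically) or a plain multi-page TIFF, in which case the
#' calibration must be supplied. Pixel values of integer-typed files are
#' recovered bit-exactly.
#'
#' @param path Path to the TIFF file.
#' @param calibration Optional list overriding or supplying
#'   \code{axis_kind}, \code{pixel_size_nm}, \code{frame_interval_s},
#'   \code{z_step_nm}, \code{channel_names}, \code{n_channels}.
#' @return An \code{image_stack}.
#' @export
read_image_stack <- function(path, calibration = NULL) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  sidecar_path <- paste0(path, ".json")
  sidecar <- if (file.exists(sidecar_path))
    jsonlite::read_json(sidecar_path, simplifyVector = TRUE) else list()
  if (!is.null(calibration)) sidecar[names(calibration)] <- calibration
  pages <- tiff::readTIFF(path, all = TRUE, info = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  shapes <- vapply(pages, function(p) paste(dim(p)[1:2], collapse = "x"), "")
  if (length(unique(shapes)) != 1L)
    stop("inconsistent page shapes in ", path, ": page ",
         which(shapes != shapes[1])[1], " is ", shapes[shapes != shapes[1]][1],
         ", expected ", shapes[1], call. = FALSE)
  if (any(vapply(pages, function(p) length(dim(p)) > 2, TRUE)))
    stop("unsupported bit depth / multi-sample page in ", path,
         ": page ", which(vapply(pages, function(p) length(dim(p)) > 2, TRUE))[1],
         call. = FALSE)
  nch <- sidecar$n_channels %||% 1L
  npl <- length(pages) / nch
  if (npl != round(npl))
    stop("page count ", length(pages), " not divisible by n_channels ", nch,
         call. = FALSE)
  scale <- sidecar$intensity_scale %||% 1
  bits <- sidecar$bits_per_sample %||% NA
  nr <- dim(pages[[1]])[1]; ncol_ <- dim(pages[[1]])[2]
  px <- array(0, dim = c(npl, nch, nr, ncol_))
  k <- 1L
  for (p in seq_len(npl)) for (ch in seq_len(nch)) {
    v <- pages[[k]] * scale
    if (identical(bits, 16L) || identical(bits, 16)) v <- round(v)
    px[p, ch, , ] <- v
    k <- k + 1L
  }
  image_stack(px,
              axis_kind = sidecar$axis_kind %||% "time",
              pixel_size_nm = sidecar$pixel_size_nm %||% 80,
              frame_interval_s = sidecar$frame_interval_s,
              z_step_nm = sidecar$z_step_nm,
              channel_names = unlist(sidecar$channel_names) %||% NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- ROI annotations -------------------------------------------------------

#' Region-of-interest annotation
#'
#' @param kind \code{"line"}, \code{"point"}, \code{"polygon"} or
#'   \code{"square"}.
#' @param frame_index 0-based frame index the ROI belongs to.
#' @param vertices Numeric matrix of (row, col) coordinates, 0-based. A
#'   square is encoded by its two opposite corners.
#' @param width_px Line width in pixels (line kind).
#' @param label Free-text label.
#' @return An object of class \code{roi_annotation}.
#' @export
roi_annotation <- function(kind = c("line", "point", "polygon", "square"),
                           frame_index = 0L, vertices, width_px = 3L,
                           label = "") {
  kind <- match.arg(kind)
  vertices <- matrix(as.numeric(vertices), ncol = 2,
                     dimnames = list(NULL, c("row", "col")))
  if (kind == "line" && nrow(vertices) < 2)
    stop("line ROI needs at least 2 vertices", call. = FALSE)
  if (kind == "square" && nrow(vertices) != 2)
    stop("square ROI is encoded by its two opposite corners", call. = FALSE)
  if (kind == "point" && nrow(vertices) != 1)
    stop("point ROI has exactly 1 vertex", call. = FALSE)
  if (frame_index < 0) stop("frame_index must be >= 0", call. = FALSE)
  if (width_px < 1) stop("width_px must be >= 1", call. = FALSE)
  structure(list(kind = kind, frame_index = as.integer(frame_index),
                 vertices = vertices, width_px = as.integer(width_px),
                 label = as.character(label)),
            class = "roi_annotation")
}

#' Load ROI annotations from CSV or JSON
#'
#' The CSV schema has columns \code{kind, frame, label, width_px, vertices},
#' vertices encoded as semicolon-separated \code{"row:col"} pairs (0-based).
#' A JSON array of objects with the same field names is also accepted.
#' Missing line widths default to \code{config$profile_width_px}.
#'
#' @param path CSV or JSON file path.
#' @param config An \code{analysis_config} supplying the default line width.
#' @param image_shape Optional \code{c(rows, cols)}; when given, vertices are
#'   validated against the image bounds.
#' @return List of \code{roi_annotation} objects.
#' @export
load_roi_annotations <- function(path, config = analysis_config(),
                                 image_shape = NULL) {
  if (!file.exists(path)) stop("ROI file not found: ", path, call. = FALSE)
  is_json <- grepl("\\.json$", path, ignore.case = TRUE)
  if (is_json) {
    recs <- jsonlite::read_json(path, simplifyVector = FALSE)
    df <- do.call(rbind, lapply(recs, function(r)
      data.frame(kind = r$kind, frame = r$frame %||% 0L,
                 label = r$label %||% "",
                 width_px = r$width_px %||% NA_integer_,
                 vertices = paste(vapply(r$vertices, function(v)
                   paste0(v[[1]], ":", v[[2]]), ""), collapse = ";"))))
    if (is.null(df)) df <- data.frame()
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE)
  }
  if (nrow(df) == 0) return(list())
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    parts <- strsplit(df$vertices[i], ";", fixed = TRUE)[[1]]
    vmat <- do.call(rbind, lapply(parts, function(s) {
      rc <- as.numeric(strsplit(s, ":", fixed = TRUE)[[1]])
      if (length(rc) != 2 || any(is.na(rc)))
        stop("record ", i, ": malformed vertex '", s, "'", call. = FALSE)
      rc
    }))
    if (!is.null(image_shape)) {
      oob <- vmat[, 1] < 0 | vmat[, 2] < 0 |
        vmat[, 1] > image_shape[1] - 1 | vmat[, 2] > image_shape[2] - 1
      if (any(oob))
        stop("record ", i, ": vertex out of image bounds (",
             paste(vmat[which(oob)[1], ], collapse = ", "), ")", call. = FALSE)
    }
    if (any(vmat < 0))
      stop("record ", i, ": vertex out of image bounds (",
           paste(vmat[which(rowSums(vmat < 0) > 0)[1], ], collapse = ", "),
           ")", call. = FALSE)
    w <- df$width_px[i]
    if (is.null(w) || is.na(w)) w <- config$profile_width_px
    out[[i]] <- roi_annotation(kind = df$kind[i],
                               frame_index = df$frame[i] %||% 0L,
                               vertices = vmat, width_px = w,
                               label = df$label[i] %||% "")
  }
  out
}

# ---- Measurement tables ----------------------------------------------------

#' Construct a measurement table
#'
#' Long-format table of scalar measurements. Columns (fixed order):
#' \code{scope, structure_id, cell_id, experiment_id, frame, metric_name,
#' value}. Missing values are encoded as \code{NA} in memory and as the
#' sentinel \code{"NA"} on disk.
#'
#' @param scope Character vector in \code{structure, tubule, cell, track,
#'   experiment}.
#' @param structure_id,cell_id,experiment_id Identifier columns (recycled).
#' @param frame Integer frame column (recycled; NA for static measurements).
#' @param metric_name Metric name column.
#' @param value Numeric values (may contain NA).
#' @return A \code{data.frame} of class \code{measurement_table}.
#' @export
measurement_table <- function(scope = character(), structure_id = NA,
                              cell_id = NA, experiment_id = NA, frame = NA,
                              metric_name = character(), value = numeric()) {
  n <- max(length(scope), length(metric_name), length(value))
  rl <- function(x, mode) {
    x <- as.vector(x, mode)
    if (n == 0L) x[0] else rep_len(x, n)
  }
  df <- data.frame(scope = rl(scope, "character"),
                   structure_id = rl(structure_id, "character"),
                   cell_id = rl(cell_id, "character"),
                   experiment_id = rl(experiment_id, "character"),
                   frame = rl(frame, "integer"),
                   metric_name = rl(metric_name, "character"),
                   value = rl(value, "numeric"),
                   stringsAsFactors = FALSE)
  ok_scope <- c("structure", "tubule", "cell", "track", "experiment")
  if (nrow(df) && !all(df$scope %in% ok_scope))
    stop("scope must be one of ", paste(ok_scope, collapse = ", "),
         call. = FALSE)
  if (any(is.infinite(df$value)))
    stop("measurement values must be finite or NA", call. = FALSE)
  class(df) <- c("measurement_table", "data.frame")
  df
}

measurement_columns <- c("scope", "structure_id", "cell_id", "experiment_id",
                         "frame", "metric_name", "value")

#' Write a measurement table to CSV
#'
#' Columns are written in the fixed documented order; \code{NA} is the
#' missing-value sentinel. \code{\link{read_measurements}} reproduces the
#' table exactly.
#'
#' @param table A \code{measurement_table}.
#' @param path Output CSV path.
#' @export
write_measurements <- function(table, path) {
  if (!all(measurement_columns %in% names(table)))
    stop("table is missing measurement columns", call. = FALSE)
  ok <- try(write.csv(table[, measurement_columns], path, row.names = FALSE,
                      na = "NA"), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("cannot write measurements to ", path, call. = FALSE)
  invisible(path)
}

#' Read a measurement table from CSV
#' @param path CSV path written by \code{\link{write_measurements}}.
#' @return A \code{measurement_table}.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("measurement file not found: ", path,
                               call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(scope = "character",
                                structure_id = "character",
                                cell_id = "character",
                                experiment_id = "character",
                                frame = "integer",
                                metric_name = "character",
                                value = "numeric"))
  measurement_table(df$scope, df$structure_id, df$cell_id, df$experiment_id,
                    df$frame, df$metric_name, df$value)
}
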