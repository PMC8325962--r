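# Segmentation of marker-positive structures and per-channel intensity
# measurement, with per-experiment normalization to control for staining
# and acquisition variation.

#' Labeled segmentation mask
#'
#' Integer label map over one image plane: 0 is background, labels 1..n are
#' 8-connected components of at least \code{min_structure_area_px} pixels,
#' numbered consecutively.
#'
#' @param labels Integer matrix of labels.
#' @return Object of class \code{label_mask}.
#' @export
label_mask <- function(labels) {
  storage.mode(labels) <- "integer"
  n <- max(labels, 0L)
  if (any(labels < 0L)) stop("labels must be >= 0", call. = FALSE)
  if (n > 0 && !all(seq_len(n) %in% labels))
    stop("labels must be consecutive from 1", call. = FALSE)
  structure(list(labels = labels, n_structures = n), class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> %d x %d px, %d structure(s)\n",
              nrow(x$labels), ncol(x$labels), x$n_structures))
  invisible(x)
}

# 8-connected component labeling (EBImage::bwlabel is 4-connected).
# Wave-style BFS: all frontier pixels expanded at once, vectorized.
label_components8 <- function(bw) {
  nr <- nrow(bw); nc <- ncol(bw)
  lab <- matrix(0L, nr, nc)
  fg <- which(bw)
  if (!length(fg)) return(lab)
  dr <- c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)
  dc <- c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)
  cur <- 0L
  for (s in fg) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    lab[s] <- cur
    frontier <- s
    while (length(frontier)) {
      fr <- ((frontier - 1L) %% nr) + 1L
      fc <- ((frontier - 1L) %/% nr) + 1L
      nxt <- integer()
      for (k in 1:8) {
        r2 <- fr + dr[k]; c2 <- fc + dc[k]
        ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
        idx <- (c2[ok] - 1L) * nr + r2[ok]
        idx <- idx[bw[idx] & lab[idx] == 0L]
        if (length(idx)) {
          lab[idx] <- cur
          nxt <- c(nxt, idx)
        }
      }
      frontier <- unique(nxt)
    }
  }
  lab
}

# drop small components and renumber consecutively from 1
prune_relabel <- function(lab, min_area) {
  if (max(lab) == 0L) return(lab)
  areas <- tabulate(lab, nbins = max(lab))
  keep <- which(areas >= min_area)
  remap <- integer(max(lab))
  remap[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  nz <- lab > 0L
  out[nz] <- remap[lab[nz]]
  out
}

#' Otsu threshold of an image plane
#'
#' Thin wrapper around \code{EBImage::otsu} operating in the plane's own
#' intensity units. A constant plane admits no threshold and is an error.
#'
#' @param plane Numeric matrix.
#' @param levels Histogram levels passed to \code{EBImage::otsu}.
#' @return Threshold value in the plane's units.
#' @export
otsu_threshold <- function(plane, levels = 256L) {
  rng <- range(plane)
  if (!all(is.finite(rng))) stop("plane must be finite", call. = FALSE)
  if (rng[1] == rng[2])
    stop("cannot compute an Otsu threshold of a constant image",
         call. = FALSE)
  EBImage::otsu(EBImage::Image((plane - rng[1]) / (rng[2] - rng[1])),
                range = c(0, 1), levels = levels) *
    (rng[2] - rng[1]) + rng[1]
}

#' Segment marker-positive structures in one plane
#'
#' Thresholds the plane (Otsu by default, or the configured absolute
#' threshold), labels 8-connected foreground components, removes components
#' smaller than \code{min_structure_area_px} ("at least five pixels" by
#' default), and renumbers labels consecutively from 1.
#'
#' @param plane Numeric matrix (one channel of one plane).
#' @param config An \code{\link{analysis_config}}.
#' @return A \code{\link{label_mask}}.
#' @export
segment_structures <- function(plane, config = analysis_config()) {
  if (!is.matrix(plane) || !all(is.finite(plane)))
    stop("plane must be a finite numeric matrix", call. = FALSE)
  th <- if (config$threshold_method == "absolute") {
    if (is.null(config$absolute_threshold))
      stop("absolute_threshold not set", call. = FALSE)
    config$absolute_threshold
  } else otsu_threshold(plane)
  bw <- plane > th
  lab <- label_components8(bw)
  lab <- prune_relabel(lab, config$min_structure_area_px)
  label_mask(lab)
}

#' Measure segmented structures in every channel
#'
#' One record per label with area, centroid (0-based row/col) and the mean
#' and sum intensity of each channel over that label's pixels.
#'
#' @param mask A \code{\link{label_mask}}.
#' @param image Numeric matrix (single channel), or 3-D array
#'   \code{[channel, row, col]}, or list of matrices.
#' @param channel_names Optional channel names for the measurement columns.
#' @param image_id Optional image identifier stored with each record.
#' @return \code{data.frame} with columns \code{structure_id, image_id,
#'   area_px, centroid_row, centroid_col, mean_<ch>, sum_<ch>}.
#' @export
measure_structures <- function(mask, image, channel_names = NULL,
                               image_id = "img") {
  stopifnot(inherits(mask, "label_mask"))
  chans <- as_channel_list(image, channel_names)
  for (ch in chans)
    if (!identical(dim(ch), dim(mask$labels)))
      stop("mask and image plane shapes differ", call. = FALSE)
  n <- mask$n_structures
  if (n == 0L)
    return(data.frame(structure_id = integer(), image_id = character(),
                      area_px = integer(), centroid_row = numeric(),
                      centroid_col = numeric()))
  lab <- mask$labels
  nz <- which(lab > 0L)
  l <- lab[nz]
  nr <- nrow(lab)
  rows0 <- ((nz - 1L) %% nr)        # 0-based
  cols0 <- ((nz - 1L) %/% nr)
  area <- tabulate(l, nbins = n)
  out <- data.frame(structure_id = seq_len(n),
                    image_id = image_id,
                    area_px = area,
                    centroid_row = as.numeric(tapply(rows0, l, mean)),
                    centroid_col = as.numeric(tapply(cols0, l, mean)))
  for (nm in names(chans)) {
    v <- chans[[nm]][nz]
    s <- as.numeric(tapply(v, l, sum))
    out[[paste0("sum_", nm)]] <- s
    out[[paste0("mean_", nm)]] <- s / area
  }
  out
}

as_channel_list <- function(image, channel_names = NULL) {
  if (is.matrix(image)) {
    chans <- list(image)
  } else if (is.list(image)) {
    chans <- image
  } else if (is.array(image) && length(dim(image)) == 3) {
    chans <- lapply(seq_len(dim(image)[1]), function(i) image[i, , ])
    names(chans) <- dimnames(image)[[1]]
  } else stop("image must be a matrix, channel list or [channel, row, col] array",
              call. = FALSE)
  if (is.null(channel_names))
    channel_names <- names(chans) %||% paste0("ch", seq_along(chans))
  else if (length(channel_names) != length(chans))
    stop("channel_names length mismatch", call. = FALSE)
  names(chans) <- channel_names
  chans
}

#' Normalize measurements by the mean of their experiment
#'
#' Divides each value by the mean of all values in the same experiment, so
#' that per-experiment normalized means equal 1. This controls for staining
#' and acquisition variation between experiments and makes experiments
#' comparable before nested (superplot) aggregation.
#'
#' @param df Data frame with at least the value and experiment columns.
#' @param value_col Name of the numeric value column.
#' @param experiment_col Name of the experiment identifier column.
#' @return \code{df} with an added column \code{<value_col>_normalized}.
#' @export
normalize_by_experiment <- function(df, value_col = "value",
                                    experiment_col = "experiment_id") {
  if (!value_col %in% names(df) || !experiment_col %in% names(df))
    stop("missing value or experiment column", call. = FALSE)
  v <- df[[value_col]]
  g <- as.character(df[[experiment_col]])
  if (!length(v)) stop("no values to normalize", call. = FALSE)
  if (any(!is.finite(v)))
    stop("values must be finite for normalization", call. = FALSE)
  means <- tapply(v, g, mean)
  zero <- names(means)[means == 0]
  if (length(zero))
    stop("experiment mean is zero for: ", paste(zero, collapse = ", "),
         call. = FALSE)
  df[[paste0(value_col, "_normalized")]] <- v / as.numeric(means[g])
  df
}
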