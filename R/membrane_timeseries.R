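# Moving circular-ROI intensity traces on the limiting membrane of tracked
# macropinosomes, with per-trace normalization and alignment of the
# reference-marker peak to a fixed time point.

#' Membrane intensity trace
#'
#' Per-frame mean intensities of a circular ROI following a marked point on
#' the limiting membrane, all channels.
#'
#' @param time_s Strictly increasing, uniformly spaced sample times (s).
#' @param values Matrix \code{time x channels} (NA = missing sample).
#' @param roi_diameter_px ROI diameter in pixels.
#' @param channel_names Channel names.
#' @param vesicle_id Identifier.
#' @param normalized Has the trace been normalized to its own mean?
#' @param align_shift_samples Whole-sample shift applied by alignment.
#' @return Object of class \code{membrane_trace}.
#' @export
membrane_trace <- function(time_s, values, roi_diameter_px = 10L,
                           channel_names = NULL,
                           vesicle_id = NA_character_, normalized = FALSE,
                           align_shift_samples = 0L) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1)
  if (length(time_s) != nrow(values))
    stop("time and value lengths differ", call. = FALSE)
  if (length(time_s) < 2) stop("trace needs >= 2 samples", call. = FALSE)
  dt <- diff(time_s)
  if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-9)
    stop("times must be strictly increasing and uniformly spaced",
         call. = FALSE)
  if (is.null(channel_names))
    channel_names <- colnames(values) %||% paste0("ch", seq_len(ncol(values)))
  colnames(values) <- channel_names
  structure(list(time_s = as.numeric(time_s), values = values,
                 roi_diameter_px = as.integer(roi_diameter_px),
                 channel_names = channel_names, vesicle_id = vesicle_id,
                 normalized = normalized,
                 align_shift_samples = as.integer(align_shift_samples)),
            class = "membrane_trace")
}

#' @export
print.membrane_trace <- function(x, ...) {
  cat(sprintf("<membrane_trace> %d samples x %d channel(s), dt = %g s%s\n",
              nrow(x$values), ncol(x$values), diff(x$time_s[1:2]),
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Sample a moving circular membrane ROI through a time-lapse
#'
#' For each marked frame, every channel is averaged over the pixels whose
#' centers lie within \code{membrane_roi_diameter_px / 2} of the mark (the
#' ten-pixel-diameter circular ROI convention). Marks must cover
#' consecutive frames. ROIs partially outside the image yield missing
#' samples.
#'
#' @param stack A time \code{\link{image_stack}}.
#' @param marks Data frame with columns \code{frame} (1-based, consecutive),
#'   \code{row}, \code{col} (0-based mark coordinates).
#' @param config An \code{\link{analysis_config}}.
#' @param vesicle_id Identifier for the trace.
#' @return A \code{\link{membrane_trace}}.
#' @export
sample_membrane_roi <- function(stack, marks, config = analysis_config(),
                                vesicle_id = NA_character_) {
  stopifnot(inherits(stack, "image_stack"))
  if (stack$axis_kind != "time")
    stop("membrane traces require a time stack", call. = FALSE)
  marks <- marks[order(marks$frame), , drop = FALSE]
  if (nrow(marks) < 2) stop("need marks on >= 2 frames", call. = FALSE)
  if (any(diff(marks$frame) != 1))
    stop("marks must cover consecutive frames", call. = FALSE)
  d <- dim(stack$pixels)
  radius <- config$membrane_roi_diameter_px / 2
  vals <- matrix(NA_real_, nrow(marks), d[2])
  for (i in seq_len(nrow(marks))) {
    ctr <- c(marks$row[i], marks$col[i])
    # ROI partially outside the image -> missing sample
    if (ctr[1] - radius < 0 || ctr[2] - radius < 0 ||
        ctr[1] + radius > d[3] - 1 || ctr[2] + radius > d[4] - 1) next
    idx <- disc_mask_idx(c(d[3], d[4]), ctr, radius)
    for (ch in seq_len(d[2])) {
      plane <- stack$pixels[marks$frame[i], ch, , ]
      vals[i, ch] <- mean(plane[idx])
    }
  }
  membrane_trace(time_s = (marks$frame - 1) * stack$frame_interval_s,
                 values = vals,
                 roi_diameter_px = config$membrane_roi_diameter_px,
                 channel_names = stack$channel_names,
                 vesicle_id = vesicle_id)
}

#' Normalize a trace against its own mean, per channel
#'
#' Divides each channel by the mean of that channel over the time series,
#' so every normalized channel has mean 1. Idempotent up to numerical
#' precision.
#'
#' @param trace A \code{\link{membrane_trace}}.
#' @return Normalized \code{membrane_trace}.
#' @export
normalize_trace <- function(trace) {
  stopifnot(inherits(trace, "membrane_trace"))
  m <- colMeans(trace$values, na.rm = TRUE)
  if (any(!is.finite(m)) || any(m <= 0))
    stop("trace mean must be positive in every channel", call. = FALSE)
  out <- trace
  out$values <- sweep(trace$values, 2, m, "/")
  out$normalized <- TRUE
  out
}

#' Align traces at the reference-channel peak and aggregate
#'
#' Each trace is shifted by whole samples (no interpolation) so that its
#' reference-channel maximum lands at the sample whose time equals
#' \code{trace_align_time_s} — index
#' \code{trace_align_time_s / frame_interval_s} — e.g. the peak is placed
#' at 15 s for 3-s acquisition. Ties go to the earliest peak; vacated
#' positions are missing. Set \code{align = FALSE} for treatments without a
#' usable peak (normalization only). Aggregation returns the per-time mean,
#' t-based 95 percent CI half-width and n over non-missing samples.
#'
#' @param traces List of \code{\link{membrane_trace}} objects (normalize
#'   first with \code{\link{normalize_trace}}; alignment and normalization
#'   commute).
#' @param reference_channel Channel whose peak defines the alignment.
#' @param config An \code{\link{analysis_config}} (alignment time).
#' @param align Align at the peak (default) or aggregate unshifted.
#' @param peak_window Optional \code{c(first, last)} 1-based sample window
#'   to search for the peak (the nascent-vesicle window); the global
#'   maximum is used when absent.
#' @return Object of class \code{trace_aggregate}: \code{time_s},
#'   \code{channel_names}, matrices \code{mean}, \code{ci_half_width},
#'   \code{n}, and the aligned \code{traces}.
#' @export
align_traces <- function(traces, reference_channel = 1L,
                         config = analysis_config(), align = TRUE,
                         peak_window = NULL) {
  if (!length(traces)) stop("need at least one trace", call. = FALSE)
  dt <- diff(traces[[1]]$time_s[1:2])
  tgt <- config$trace_align_time_s / dt
  if (align && abs(tgt - round(tgt)) > 1e-9)
    stop("trace_align_time_s (", config$trace_align_time_s,
         " s) is not a multiple of the frame interval (", dt, " s)",
         call. = FALSE)
  tgt <- as.integer(round(tgt)) + 1L       # 1-based target sample
  L <- max(vapply(traces, function(x) nrow(x$values), 1L))
  nch <- ncol(traces[[1]]$values)
  chn <- traces[[1]]$channel_names
  arr <- array(NA_real_, dim = c(L, nch, length(traces)))
  aligned <- vector("list", length(traces))
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    ni <- nrow(tr$values)
    shift <- 0L
    if (align) {
      ref <- tr$values[, if (is.character(reference_channel))
        match(reference_channel, tr$channel_names) else reference_channel]
      win <- if (is.null(peak_window)) seq_len(ni) else
        seq(max(1L, peak_window[1]), min(ni, peak_window[2]))
      if (all(is.na(ref[win])))
        stop("trace ", i, ": reference channel all missing in peak window",
             call. = FALSE)
      peak <- win[which.max(ref[win])]     # earliest on ties
      shift <- tgt - peak
    }
    shifted <- matrix(NA_real_, L, nch)
    dst <- seq_len(ni) + shift
    keep <- dst >= 1L & dst <= L
    shifted[dst[keep], ] <- tr$values[which(keep), ]
    arr[, , i] <- shifted
    aligned[[i]] <- membrane_trace(time_s = (seq_len(L) - 1) * dt,
                                   values = shifted,
                                   roi_diameter_px = tr$roi_diameter_px,
                                   channel_names = chn,
                                   vesicle_id = tr$vesicle_id,
                                   normalized = tr$normalized,
                                   align_shift_samples = shift)
  }
  nmat <- apply(!is.na(arr), c(1, 2), sum)
  mmat <- apply(arr, c(1, 2), function(v) mean(v, na.rm = TRUE))
  mmat[nmat == 0] <- NA_real_
  sdm <- apply(arr, c(1, 2), function(v) stats::sd(v, na.rm = TRUE))
  ci <- matrix(NA_real_, L, nch)        # undefined CI flagged NA when n < 2
  has <- nmat >= 2
  ci[has] <- stats::qt(0.975, nmat[has] - 1) * sdm[has] / sqrt(nmat[has])
  colnames(mmat) <- colnames(ci) <- colnames(nmat) <- chn
  structure(list(time_s = (seq_len(L) - 1) * dt, channel_names = chn,
                 mean = mmat, ci_half_width = ci, n = nmat,
                 traces = aligned),
            class = "trace_aggregate")
}

#' Export a trace aggregate as CSV
#'
#' Columns: \code{time_s, channel, mean, ci_half_width, n}.
#'
#' @param aggregate A \code{trace_aggregate}.
#' @param path Output CSV path.
#' @export
write_trace_aggregate <- function(aggregate, path) {
  stopifnot(inherits(aggregate, "trace_aggregate"))
  rows <- do.call(rbind, lapply(seq_along(aggregate$channel_names),
    function(ci) data.frame(time_s = aggregate$time_s,
                            channel = aggregate$channel_names[ci],
                            mean = aggregate$mean[, ci],
                            ci_half_width = aggregate$ci_half_width[, ci],
                            n = aggregate$n[, ci])))
  write.csv(rows, path, row.names = FALSE, na = "NA")
  invisible(path)
}
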