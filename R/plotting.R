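# Base-graphics methods for the aggregate objects.

#' @export
print.aligned_profiles <- function(x, ...) {
  cat(sprintf("<aligned_profiles> %d profile(s), %d positions, centre %d\n",
              length(x$profiles), length(x$positions), x$center_index))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.trace_aggregate <- function(x, ...) {
  cat(sprintf("<trace_aggregate> %d trace(s), %d timepoints (%g-%g s)\n",
              length(x$traces), length(x$time_s), min(x$time_s),
              max(x$time_s)))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

# shared mean +/- CI ribbon plot
plot_band <- function(xv, m, ci, xlab, ylab, main, col) {
  ok <- is.finite(m)
  graphics::plot(xv[ok], m[ok], type = "n", xlab = xlab, ylab = ylab,
                 main = main,
                 ylim = range(c(m[ok] - ci[ok], m[ok] + ci[ok], m[ok]),
                              na.rm = TRUE))
  band <- ok & is.finite(ci)
  if (any(band))
    graphics::polygon(c(xv[band], rev(xv[band])),
                      c(m[band] - ci[band], rev(m[band] + ci[band])),
                      col = grDevices::adjustcolor(col, 0.25), border = NA)
  graphics::lines(xv[ok], m[ok], col = col, lwd = 2)
}

#' Plot an aligned cross-tubule profile aggregate
#'
#' Mean fold-change with the 95 percent CI ribbon per channel; the dashed
#' vertical line marks the aligned peak position, the dotted horizontal
#' line the cytoplasmic baseline (fold-change 1).
#'
#' @param x An \code{aligned_profiles} object.
#' @param channels Channels to draw (default: all).
#' @param ... Ignored.
#' @export
plot.aligned_profiles <- function(x, channels = x$channel_names, ...) {
  cols <- grDevices::hcl.colors(max(2L, length(channels)), "Dark 3")
  first <- TRUE
  for (i in seq_along(channels)) {
    ci <- match(channels[i], x$channel_names)
    if (first) {
      plot_band(x$positions, x$mean[, ci], x$ci_half_width[, ci],
                "position (px)", "fold-change over background",
                "aligned membrane profiles", cols[i])
      graphics::abline(v = x$center_index, lty = 2, col = "grey40")
      graphics::abline(h = 1, lty = 3, col = "grey40")
      first <- FALSE
    } else {
      ok <- is.finite(x$mean[, ci])
      graphics::lines(x$positions[ok], x$mean[ok, ci], col = cols[i],
                      lwd = 2)
    }
  }
  graphics::legend("topright", legend = channels, lwd = 2,
                   col = cols[seq_along(channels)], bty = "n")
  invisible(x)
}

#' Plot a membrane-trace aggregate
#'
#' Per-time mean with the 95 percent CI ribbon per channel; the dashed
#' vertical line marks the alignment time.
#'
#' @param x A \code{trace_aggregate} object.
#' @param channels Channels to draw (default: all).
#' @param align_time_s Optional alignment time to mark.
#' @param ... Ignored.
#' @export
plot.trace_aggregate <- function(x, channels = x$channel_names,
                                 align_time_s = NULL, ...) {
  cols <- grDevices::hcl.colors(max(2L, length(channels)), "Dark 3")
  first <- TRUE
  for (i in seq_along(channels)) {
    ci <- match(channels[i], x$channel_names)
    if (first) {
      plot_band(x$time_s, x$mean[, ci], x$ci_half_width[, ci],
                "time (s)", "normalized intensity",
                "membrane recruitment traces", cols[i])
      if (!is.null(align_time_s))
        graphics::abline(v = align_time_s, lty = 2, col = "grey40")
      first <- FALSE
    } else {
      ok <- is.finite(x$mean[, ci])
      graphics::lines(x$time_s[ok], x$mean[ok, ci], col = cols[i], lwd = 2)
    }
  }
  graphics::legend("topright", legend = channels, lwd = 2,
                   col = cols[seq_along(channels)], bty = "n")
  invisible(x)
}
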