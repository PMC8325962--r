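# Whole-cell and per-organelle fluid-phase (dextran) quantification and
# masked Pearson colocalization.

#' Sum-project a z-stack
#'
#' Pixelwise sum across z for every channel — the projection used for
#' whole-cell fluid-phase measurements.
#'
#' @param zstack A z \code{\link{image_stack}}.
#' @return Array \code{[channel, row, col]}.
#' @export
sum_projection <- function(zstack) {
  stopifnot(inherits(zstack, "image_stack"))
  if (zstack$axis_kind != "z")
    stop("sum projection requires a z stack", call. = FALSE)
  d <- dim(zstack$pixels)
  out <- array(0, dim = d[2:4])
  for (ch in seq_len(d[2]))
    out[ch, , ] <- apply(zstack$pixels[, ch, , , drop = FALSE], c(3, 4), sum)
  dimnames(out) <- list(zstack$channel_names, NULL, NULL)
  out
}

#' Background-subtracted whole-cell dextran total
#'
#' Total in-mask dextran minus the background mean (estimated in a square
#' outside all cells) times the in-mask pixel count. Reported raw: low
#' signal may yield negative totals, which are not clamped so that
#' per-experiment averages stay unbiased.
#'
#' @param projection Matrix (the dextran channel of a sum projection).
#' @param cell_mask Logical matrix of the traced cell outline.
#' @param background_square A square \code{\link{roi_annotation}} outside
#'   all cells.
#' @return Background-subtracted summed intensity.
#' @export
whole_cell_dextran <- function(projection, cell_mask, background_square) {
  stopifnot(inherits(background_square, "roi_annotation"),
            background_square$kind == "square")
  v <- background_square$vertices
  r0 <- floor(min(v[, 1])) + 1L; r1 <- floor(max(v[, 1])) + 1L
  c0 <- floor(min(v[, 2])) + 1L; c1 <- floor(max(v[, 2])) + 1L
  if (r0 < 1 || c0 < 1 || r1 > nrow(projection) || c1 > ncol(projection))
    stop("background square outside the image", call. = FALSE)
  if (any(cell_mask[r0:r1, c0:c1]))
    stop("background square overlaps a cell mask", call. = FALSE)
  bg <- mean(projection[r0:r1, c0:c1])
  sum(projection[cell_mask]) - bg * sum(cell_mask)
}

#' Index of the most in-focus plane of a z-stack
#'
#' Maximizes the normalized intensity variance (variance / mean^2), a
#' standard autofocus criterion; ties go to the lowest index.
#'
#' @param zstack A z \code{\link{image_stack}}.
#' @param channel Channel used for the focus metric.
#' @return 1-based plane index.
#' @export
best_focus_plane <- function(zstack, channel = 1L) {
  stopifnot(inherits(zstack, "image_stack"))
  ch <- resolve_channel(zstack, channel)
  score <- vapply(seq_len(dim(zstack$pixels)[1]), function(p) {
    v <- zstack$pixels[p, ch, , ]
    m <- mean(v)
    if (m == 0) 0 else stats::var(as.vector(v)) / m^2
  }, 1)
  which.max(score)   # which.max returns the first (lowest) index on ties
}

#' Dextran content of marker-positive organelles in one cell
#'
#' Segments the organelle channel inside the cell mask (minimum area
#' five pixels by default) and sums the dextran channel over all organelle
#' pixels. Per-experiment normalization is applied downstream via
#' \code{\link{normalize_by_experiment}}.
#'
#' @param plane Array \code{[channel, row, col]}, channel list, or matrix
#'   pair — the in-focus plane.
#' @param organelle_channel Name/index of the organelle marker channel.
#' @param dextran_channel Name/index of the dextran channel.
#' @param cell_mask Logical matrix restricting segmentation to one cell.
#' @param config An \code{\link{analysis_config}}.
#' @param cell_id,experiment_id Identifiers for the record.
#' @param channel_names Channel names when \code{plane} is an unnamed array.
#' @return Data frame (one row): \code{cell_id, experiment_id,
#'   organelle_dextran, n_organelles}.
#' @export
organelle_dextran <- function(plane, organelle_channel, dextran_channel,
                              cell_mask = NULL, config = analysis_config(),
                              cell_id = "cell1", experiment_id = "E1",
                              channel_names = NULL) {
  chans <- as_channel_list(plane, channel_names)
  if (is.numeric(organelle_channel)) organelle_channel <-
      names(chans)[organelle_channel]
  if (is.numeric(dextran_channel)) dextran_channel <-
      names(chans)[dextran_channel]
  org <- chans[[organelle_channel]]
  dex <- chans[[dextran_channel]]
  if (is.null(org) || is.null(dex))
    stop("organelle or dextran channel not found", call. = FALSE)
  if (!is.null(cell_mask)) {
    masked <- org
    masked[!cell_mask] <- min(org)
  } else masked <- org
  mask <- tryCatch(segment_structures(masked, config),
                   error = function(e) label_mask(matrix(0L, nrow(org),
                                                         ncol(org))))
  if (mask$n_structures == 0L)
    return(data.frame(cell_id = cell_id, experiment_id = experiment_id,
                      organelle_dextran = 0, n_organelles = 0L))
  sel <- mask$labels > 0L
  if (!is.null(cell_mask)) sel <- sel & cell_mask
  data.frame(cell_id = cell_id, experiment_id = experiment_id,
             organelle_dextran = sum(dex[sel]),
             n_organelles = mask$n_structures)
}

#' Masked Pearson colocalization coefficient
#'
#' Standard Pearson correlation of two channels over the in-mask pixels.
#'
#' @param ch1,ch2 Numeric matrices of equal shape.
#' @param mask Logical matrix selecting the pixels (default: all).
#' @return Correlation in [-1, 1].
#' @export
pearson_coloc <- function(ch1, ch2, mask = NULL) {
  if (!identical(dim(ch1), dim(ch2)))
    stop("channel shapes differ", call. = FALSE)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(ch1), ncol(ch1))
  x <- ch1[mask]; y <- ch2[mask]
  if (length(x) < 2)
    stop("need at least 2 in-mask pixels", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: a channel is constant within the mask",
         call. = FALSE)
  stats::cor(x, y)
}
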