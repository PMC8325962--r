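# Membrane-contour and cross-tubule intensity profiling: the
# coefficient-of-variation tubulation statistic, peak-aligned fold-change
# profiles, and the fold-over-background tubule positivity classifier.

#' Intensity profile along or across a membrane
#'
#' Ordered width-averaged intensity samples, one per position at ~1 px
#' spacing. Produced by \code{\link{contour_profile}} (around a closed
#' limiting-membrane contour) or \code{\link{line_roi_profile}} (across a
#' tubule). Missing samples (band leaving the image) are \code{NA}.
#'
#' @param values Numeric vector (one channel) or matrix
#'   \code{positions x channels}.
#' @param width_px Averaging width in pixels.
#' @param channel_names Optional channel names (matrix columns).
#' @param vesicle_id Optional identifier.
#' @param diameter_um Diameter of the profiled vesicle, if known (used for
#'   CV eligibility).
#' @param alignment_offset Samples the profile has been shifted by.
#' @param background Per-channel background the profile was normalized by
#'   (NA before normalization).
#' @return Object of class \code{line_profile}.
#' @export
line_profile <- function(values, width_px = 3L, channel_names = NULL,
                         vesicle_id = NA_character_, diameter_um = NA_real_,
                         alignment_offset = 0L, background = NA_real_) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1)
  if (is.null(channel_names))
    channel_names <- colnames(values) %||% paste0("ch", seq_len(ncol(values)))
  colnames(values) <- channel_names
  if (width_px < 1) stop("width_px must be >= 1", call. = FALSE)
  structure(list(positions_px = seq_len(nrow(values)) - 1L,
                 values = values, width_px = as.integer(width_px),
                 channel_names = channel_names,
                 vesicle_id = vesicle_id, diameter_um = diameter_um,
                 alignment_offset = as.integer(alignment_offset),
                 background = background),
            class = "line_profile")
}

#' @export
print.line_profile <- function(x, ...) {
  cat(sprintf("<line_profile> %d samples x %d channel(s), width %d px\n",
              nrow(x$values), ncol(x$values), x$width_px))
  invisible(x)
}

profile_channel <- function(profile, channel) {
  if (is.character(channel)) {
    i <- match(channel, profile$channel_names)
    if (is.na(i)) stop("unknown channel: ", channel, call. = FALSE)
  } else i <- as.integer(channel)
  profile$values[, i]
}

# ---- contour extraction ----------------------------------------------------

#' Closed membrane contour of a segmented vesicle
#'
#' @param points Nx2 matrix of 0-based (row, col) coordinates; the path is
#'   closed (last point joins the first).
#' @param diameter_um Area-equivalent diameter in um.
#' @param vesicle_id Identifier.
#' @return Object of class \code{membrane_contour}.
#' @export
membrane_contour <- function(points, diameter_um, vesicle_id = NA_character_) {
  points <- matrix(as.numeric(points), ncol = 2,
                   dimnames = list(NULL, c("row", "col")))
  if (nrow(points) < 8)
    stop("contour needs at least 8 points", call. = FALSE)
  structure(list(vesicle_id = vesicle_id, points = points,
                 diameter_um = diameter_um),
            class = "membrane_contour")
}

#' Arc length of a closed contour (px)
#' @param contour A \code{membrane_contour}.
#' @return Perimeter in pixels.
#' @export
contour_length <- function(contour) {
  p <- contour$points
  q <- rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE])
  sum(sqrt(rowSums((q - p)^2)))
}

#' Trace the limiting-membrane contour of one labeled structure
#'
#' Extracts the outer boundary of the (hole-filled) structure, smooths it
#' with a short circular moving average for sub-pixel placement, orients it
#' counter-clockwise starting from the boundary point nearest the image
#' origin, and resamples it to ~1 px arc-length spacing. The diameter is
#' the area-equivalent circle diameter,
#' \code{2 * sqrt(area / pi) * pixel_size_nm / 1000} um.
#'
#' @param mask A \code{\link{label_mask}}.
#' @param label Which structure to trace.
#' @param pixel_size_nm Lateral calibration.
#' @return A \code{\link{membrane_contour}}.
#' @export
extract_contour <- function(mask, label, pixel_size_nm = 80) {
  stopifnot(inherits(mask, "label_mask"))
  if (label < 1 || label > mask$n_structures)
    stop("label ", label, " not present in mask", call. = FALSE)
  bw <- mask$labels == label
  nr <- nrow(bw); nc <- ncol(bw)
  if (any(bw[1, ]) || any(bw[nr, ]) || any(bw[, 1]) || any(bw[, nc]))
    stop("structure touches the image border; circumference incomplete",
         call. = FALSE)
  filled <- EBImage::imageData(EBImage::fillHull(EBImage::Image(bw * 1)))
  area <- sum(filled > 0)
  dia_um <- 2 * sqrt(area / pi) * pixel_size_nm / 1000
  oc <- EBImage::ocontour(EBImage::Image(filled))
  if (!length(oc))
    stop("no boundary found for label ", label, call. = FALSE)
  pts <- oc[[which.max(vapply(oc, nrow, 1L))]]  # 0-based (row, col)
  pts <- matrix(as.numeric(pts), ncol = 2)
  if (nrow(pts) < 8)
    stop("structure below resolvable circumference (", nrow(pts),
         " boundary points)", call. = FALSE)
  # circular moving-average smoothing (window 3) for sub-pixel placement
  sm <- function(v) (v + c(tail(v, 1), head(v, -1)) +
                       c(tail(v, -1), head(v, 1))) / 3
  pts <- cbind(sm(pts[, 1]), sm(pts[, 2]))
  # orient counter-clockwise (positive shoelace area in (col, -row) frame)
  nxt <- rbind(pts[-1, ], pts[1, ])
  signed2 <- sum(pts[, 2] * (-nxt[, 1]) - nxt[, 2] * (-pts[, 1]))
  if (signed2 < 0) pts <- pts[nrow(pts):1, , drop = FALSE]
  # start at boundary point nearest the image origin
  start <- which.min(pts[, 1]^2 + pts[, 2]^2)
  if (start > 1) pts <- rbind(pts[start:nrow(pts), , drop = FALSE],
                              pts[seq_len(start - 1), , drop = FALSE])
  # resample to ~1 px arc-length spacing
  closed <- rbind(pts, pts[1, ])
  seglen <- sqrt(rowSums(diff(closed)^2))
  arc <- c(0, cumsum(seglen))
  per <- arc[length(arc)]
  n_out <- max(8L, round(per))
  s_out <- seq(0, per, length.out = n_out + 1)[seq_len(n_out)]
  rs <- cbind(stats::approx(arc, closed[, 1], xout = s_out)$y,
              stats::approx(arc, closed[, 2], xout = s_out)$y)
  membrane_contour(rs, diameter_um = dia_um,
                   vesicle_id = as.character(label))
}

#' Snap a contour onto the membrane intensity ridge
#'
#' Moves each contour point along its local normal to the position of
#' maximum intensity within \code{search_px}, then re-smooths — emulating a
#' line drawn around the circumference that follows the limiting membrane
#' rather than the segmentation iso-level, which sits on the outer
#' intensity slope.
#'
#' @param image Numeric matrix (the membrane channel).
#' @param contour A \code{\link{membrane_contour}}.
#' @param search_px Search range along the normal, both directions.
#' @param step Sub-pixel sampling step.
#' @return The refined \code{membrane_contour} (diameter unchanged).
#' @export
snap_contour_to_ridge <- function(image, contour, search_px = 4, step = 0.25) {
  stopifnot(inherits(contour, "membrane_contour"))
  p <- contour$points
  n <- nrow(p)
  nxt <- rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE])
  prv <- rbind(p[n, , drop = FALSE], p[-n, , drop = FALSE])
  tang <- nxt - prv
  tlen <- sqrt(rowSums(tang^2)); tlen[tlen == 0] <- 1
  nrm <- cbind(-tang[, 2], tang[, 1]) / tlen
  offs <- seq(-search_px, search_px, by = step)
  best <- rep(0, n)
  bestv <- rep(-Inf, n)
  for (o in offs) {
    v <- bilinear_sample(image, p[, 1] + o * nrm[, 1], p[, 2] + o * nrm[, 2])
    upd <- !is.na(v) & v > bestv
    best[upd] <- o
    bestv[upd] <- v[upd]
  }
  q <- p + best * nrm
  sm <- function(v) (v + c(tail(v, 1), head(v, -1)) +
                       c(tail(v, -1), head(v, 1))) / 3
  out <- contour
  out$points <- cbind(sm(q[, 1]), sm(q[, 2]))
  out
}

# bilinear interpolation at 0-based (row, col); NA outside the image
bilinear_sample <- function(img, r, c) {
  nr <- nrow(img); nc <- ncol(img)
  out <- rep(NA_real_, length(r))
  ok <- r >= 0 & c >= 0 & r <= nr - 1 & c <= nc - 1
  if (!any(ok)) return(out)
  r <- pmin(r[ok], nr - 1 - 1e-9); c <- pmin(c[ok], nc - 1 - 1e-9)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  i00 <- (c0) * nr + r0 + 1
  v <- img[i00] * (1 - fr) * (1 - fc) + img[i00 + 1] * fr * (1 - fc) +
    img[i00 + nr] * (1 - fr) * fc + img[i00 + nr + 1] * fr * fc
  out[ok] <- v
  out
}

#' Width-averaged intensity profile around a membrane contour
#'
#' At each contour sample the intensity is the mean of \code{width_px}
#' bilinear samples spaced 1 px along the local normal, centred on the
#' path — the same measurement as a 3-px-wide line drawn around the
#' circumference. Samples whose normal band leaves the image are \code{NA}.
#'
#' @param image Matrix, \code{[channel, row, col]} array or channel list.
#' @param contour A \code{\link{membrane_contour}}.
#' @param width_px Band width (default 3).
#' @param channel_names Optional channel names.
#' @return A \code{\link{line_profile}} carrying the contour's diameter.
#' @export
contour_profile <- function(image, contour, width_px = 3L,
                            channel_names = NULL) {
  stopifnot(inherits(contour, "membrane_contour"))
  chans <- as_channel_list(image, channel_names)
  p <- contour$points
  n <- nrow(p)
  nxt <- rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE])
  prv <- rbind(p[n, , drop = FALSE], p[-n, , drop = FALSE])
  tang <- nxt - prv
  tlen <- sqrt(rowSums(tang^2)); tlen[tlen == 0] <- 1
  nrm <- cbind(-tang[, 2], tang[, 1]) / tlen
  offs <- seq_len(width_px) - (width_px + 1) / 2
  vals <- matrix(NA_real_, n, length(chans))
  for (ci in seq_along(chans)) {
    acc <- matrix(NA_real_, n, length(offs))
    for (k in seq_along(offs))
      acc[, k] <- bilinear_sample(chans[[ci]],
                                  p[, 1] + offs[k] * nrm[, 1],
                                  p[, 2] + offs[k] * nrm[, 2])
    vals[, ci] <- rowMeans(acc)   # NA when any band sample leaves the image
  }
  line_profile(vals, width_px = width_px, channel_names = names(chans),
               vesicle_id = contour$vesicle_id,
               diameter_um = contour$diameter_um)
}

#' Width-averaged intensity profile along a line ROI
#'
#' Samples a straight (or polyline) ROI at 1 px arc-length spacing,
#' averaging \code{width_px} bilinear samples along the local normal at
#' each position — the measurement of a three-pixel-wide line drawn across
#' a tubule.
#'
#' @param image Matrix, \code{[channel, row, col]} array or channel list.
#' @param roi A line \code{\link{roi_annotation}}.
#' @param channel_names Optional channel names.
#' @return A \code{\link{line_profile}}.
#' @export
line_roi_profile <- function(image, roi, channel_names = NULL) {
  stopifnot(inherits(roi, "roi_annotation"))
  if (roi$kind != "line") stop("roi must be a line annotation", call. = FALSE)
  chans <- as_channel_list(image, channel_names)
  v <- roi$vertices
  seglen <- sqrt(rowSums(diff(v)^2))
  arc <- c(0, cumsum(seglen))
  n <- max(2L, round(arc[length(arc)]) + 1L)
  s <- seq(0, arc[length(arc)], length.out = n)
  pts <- cbind(stats::approx(arc, v[, 1], xout = s)$y,
               stats::approx(arc, v[, 2], xout = s)$y)
  # open path: tangents by central differences, one-sided at the ends
  npt <- nrow(pts)
  tang <- pts[pmin(seq_len(npt) + 1L, npt), , drop = FALSE] -
    pts[pmax(seq_len(npt) - 1L, 1L), , drop = FALSE]
  tlen <- sqrt(rowSums(tang^2)); tlen[tlen == 0] <- 1
  nrm <- cbind(-tang[, 2], tang[, 1]) / tlen
  offs <- seq_len(roi$width_px) - (roi$width_px + 1) / 2
  vals <- matrix(NA_real_, npt, length(chans))
  for (ci in seq_along(chans)) {
    acc <- matrix(NA_real_, npt, length(offs))
    for (k in seq_along(offs))
      acc[, k] <- bilinear_sample(chans[[ci]],
                                  pts[, 1] + offs[k] * nrm[, 1],
                                  pts[, 2] + offs[k] * nrm[, 2])
    vals[, ci] <- rowMeans(acc)
  }
  line_profile(vals, width_px = roi$width_px, channel_names = names(chans),
               vesicle_id = roi$label)
}

# ---- CV tubulation statistic ----------------------------------------------

#' Coefficient of variation of intensity along the membrane circumference
#'
#' The tubulation statistic: sample standard deviation divided by mean of
#' the selected channel's samples along the closed contour. Tubule
#' nucleation forms bright spots directly at the limiting membrane, so more
#' nucleation raises the circumferential CV. Only macropinosomes larger
#' than \code{min_macropinosome_diameter_um} (default 1 um) are eligible;
#' profiles with unknown diameter are accepted.
#'
#' @param profile A \code{\link{line_profile}} around the circumference.
#' @param channel Channel name or index to evaluate.
#' @param config An \code{\link{analysis_config}}; sets the eligibility
#'   diameter and the SD denominator convention (sample, n-1, by default).
#' @return CV (dimensionless).
#' @export
tubulation_cv <- function(profile, channel = 1L, config = analysis_config()) {
  stopifnot(inherits(profile, "line_profile"))
  if (!is.na(profile$diameter_um) &&
      profile$diameter_um <= config$min_macropinosome_diameter_um)
    stop("vesicle diameter ", signif(profile$diameter_um, 3),
         " um is not above the eligibility minimum of ",
         config$min_macropinosome_diameter_um, " um", call. = FALSE)
  v <- profile_channel(profile, channel)
  v <- v[!is.na(v)]
  if (length(v) < 2)
    stop("need at least 2 non-missing samples", call. = FALSE)
  m <- mean(v)
  if (m == 0) stop("profile mean is zero; CV undefined", call. = FALSE)
  s <- stats::sd(v)
  if (config$cv_sd_denominator == "n")
    s <- s * sqrt((length(v) - 1) / length(v))
  s / m
}

# ---- tubule detection ------------------------------------------------------

# Zhang-Suen thinning of a logical matrix to a 1-px skeleton
zhang_suen_thin <- function(bw) {
  img <- matrix(as.integer(bw), nrow(bw), ncol(bw))
  pad <- matrix(0L, nrow(img) + 2, ncol(img) + 2)
  pad[2:(nrow(img) + 1), 2:(ncol(img) + 1)] <- img
  nr <- nrow(pad); nc <- ncol(pad)
  shift <- function(m, dr, dc) {
    out <- matrix(0L, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p2 <- shift(pad, 1, 0); p3 <- shift(pad, 1, -1); p4 <- shift(pad, 0, -1)
      p5 <- shift(pad, -1, -1); p6 <- shift(pad, -1, 0); p7 <- shift(pad, -1, 1)
      p8 <- shift(pad, 0, 1); p9 <- shift(pad, 1, 1)
      bsum <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqs <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      a <- matrix(0L, nr, nc)
      for (i in 1:8) a <- a + (seqs[[i]] == 0L & seqs[[i + 1]] == 1L)
      if (step == 1) {
        cond <- pad == 1L & bsum >= 2L & bsum <= 6L & a == 1L &
          (p2 * p4 * p6 == 0L) & (p4 * p6 * p8 == 0L)
      } else {
        cond <- pad == 1L & bsum >= 2L & bsum <= 6L & a == 1L &
          (p2 * p4 * p8 == 0L) & (p2 * p6 * p8 == 0L)
      }
      if (any(cond)) { pad[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  pad[2:(nrow(img) + 1), 2:(ncol(img) + 1)] > 0L
}

# geodesic distances within a pixel set from a source pixel (8-conn,
# diagonal steps cost sqrt(2)); px is an n x 2 matrix of 1-based coords
geodesic_dists <- function(px, source_idx) {
  n <- nrow(px)
  d <- rep(Inf, n); d[source_idx] <- 0
  # adjacency on the fly: pixels within chebyshev distance 1
  done <- rep(FALSE, n)
  for (iter in seq_len(n)) {
    u <- which.min(ifelse(done, Inf, d))
    if (!is.finite(d[u])) break
    done[u] <- TRUE
    dr <- abs(px[, 1] - px[u, 1]); dc <- abs(px[, 2] - px[u, 2])
    nb <- which(!done & dr <= 1 & dc <= 1 & (dr + dc) > 0)
    if (length(nb)) {
      w <- ifelse(dr[nb] + dc[nb] == 2, sqrt(2), 1)
      d[nb] <- pmin(d[nb], d[u] + w)
    }
  }
  d
}

#' Detect tubule protrusions on a vesicle mask
#'
#' Protrusions are the mask minus its morphological opening with a disc
#' sized from the vesicle body (the maximal inscribed radius); each
#' protrusion is thinned to a skeleton and measured as the geodesic length
#' from its root on the body to its tip. Only tubules strictly longer than
#' \code{tubule_min_length_px} ("exceeded six pixels in length") are
#' returned.
#'
#' @param mask Logical matrix (vesicle including protrusions), or a
#'   \code{\link{label_mask}} whose nonzero pixels are used.
#' @param config An \code{\link{analysis_config}}.
#' @return List of tubules, each \code{list(tubule_id, root, tip,
#'   skeleton_px, length_px)}; coordinates 0-based. Empty list when no
#'   protrusion exceeds the length cut.
#' @export
detect_tubules <- function(mask, config = analysis_config()) {
  if (inherits(mask, "label_mask")) mask <- mask$labels > 0L
  if (!is.logical(mask)) mask <- mask > 0
  if (!any(mask)) return(list())
  filled <- EBImage::imageData(EBImage::fillHull(EBImage::Image(mask * 1))) > 0
  dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(filled * 1)))
  r_in <- max(dm)
  open_r <- max(2L, floor(r_in * 0.7))
  brush <- EBImage::makeBrush(2L * open_r + 1L, shape = "disc")
  body <- EBImage::imageData(EBImage::opening(EBImage::Image(filled * 1),
                                              brush)) > 0
  if (!any(body)) body <- dm >= r_in  # degenerate: tiny structure
  protr <- filled & !body
  if (!any(protr)) return(list())
  # distance of every non-body pixel to the body
  dist_body <- EBImage::imageData(
    EBImage::distmap(EBImage::Image((!body) * 1)))
  lab <- label_components8(protr)
  out <- list()
  tid <- 0L
  for (l in seq_len(max(lab))) {
    comp <- which(lab == l, arr.ind = TRUE)
    if (nrow(comp) < 2) next
    # length: farthest reach of the protrusion from the vesicle body. The
    # thresholded tip extends past the true tip by the same intensity tail
    # that the body extends past the limiting membrane, so the two cancel.
    db_comp <- dist_body[comp]
    len <- max(db_comp)
    if (!is.finite(len) || len <= config$tubule_min_length_px) next
    cm <- matrix(FALSE, nrow(mask), ncol(mask))
    cm[comp] <- TRUE
    sk <- zhang_suen_thin(cm)
    skpx <- which(sk, arr.ind = TRUE)
    if (nrow(skpx) < 2) skpx <- comp
    root_i <- which.min(dist_body[skpx])
    tid <- tid + 1L
    out[[tid]] <- list(tubule_id = tid,
                       root = as.numeric(skpx[root_i, ]) - 1,
                       tip = as.numeric(comp[which.max(db_comp), ]) - 1,
                       skeleton_px = unname(skpx) - 1L,
                       length_px = len)
  }
  out
}

# ---- cytoplasmic background ------------------------------------------------

#' Cytoplasmic background from a square region
#'
#' Mean fluorescence in a square of side \code{background_square_px}
#' (default 100 px). The square is either supplied as a square ROI or
#' placed automatically: the first (raster-order) position lying fully
#' inside \code{cell_mask} and off \code{exclude_mask} (segmented
#' structures). Supplying a square that overlaps excluded pixels is an
#' error in strict mode.
#'
#' @param plane Numeric matrix (the background channel).
#' @param square Optional square \code{\link{roi_annotation}}.
#' @param config An \code{\link{analysis_config}}.
#' @param cell_mask Optional logical matrix the square must lie inside.
#' @param exclude_mask Optional logical matrix of pixels to avoid.
#' @param strict Error (rather than warn) when a supplied square overlaps
#'   \code{exclude_mask}.
#' @return Mean intensity over the square.
#' @export
cytoplasmic_background <- function(plane, square = NULL,
                                   config = analysis_config(),
                                   cell_mask = NULL, exclude_mask = NULL,
                                   strict = TRUE) {
  nr <- nrow(plane); nc <- ncol(plane)
  if (!is.null(square)) {
    stopifnot(inherits(square, "roi_annotation"), square$kind == "square")
    v <- square$vertices
    r0 <- floor(min(v[, 1])) + 1L; r1 <- floor(max(v[, 1])) + 1L
    c0 <- floor(min(v[, 2])) + 1L; c1 <- floor(max(v[, 2])) + 1L
    if (r0 < 1 || c0 < 1 || r1 > nr || c1 > nc)
      stop("background square outside the image", call. = FALSE)
    if (!is.null(exclude_mask) && any(exclude_mask[r0:r1, c0:c1])) {
      msg <- "background square overlaps segmented structures"
      if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
    }
    return(mean(plane[r0:r1, c0:c1]))
  }
  side <- config$background_square_px
  if (side > nr || side > nc)
    stop("no valid background placement: square larger than image",
         call. = FALSE)
  good <- matrix(TRUE, nr, nc)
  if (!is.null(cell_mask)) good <- good & cell_mask
  if (!is.null(exclude_mask)) good <- good & !exclude_mask
  # integral image: a placement is valid iff all side^2 pixels are good
  ii <- apply(apply(good, 2, cumsum), 1, cumsum)  # ii[c, r] after t()
  ii <- t(ii)
  win_sum <- function(r, c) {                     # top-left (r, c), 1-based
    r2 <- r + side - 1L; c2 <- c + side - 1L
    ii[r2, c2] -
      (if (r > 1) ii[r - 1, c2] else 0) -
      (if (c > 1) ii[r2, c - 1] else 0) +
      (if (r > 1 && c > 1) ii[r - 1, c - 1] else 0)
  }
  for (c in seq_len(nc - side + 1L)) for (r in seq_len(nr - side + 1L)) {
    if (win_sum(r, c) == side * side)
      return(mean(plane[r:(r + side - 1L), c:(c + side - 1L)]))
  }
  stop("no valid background placement found", call. = FALSE)
}

# ---- tubule classification -------------------------------------------------

#' Classify tubules as marker-positive by fold over cytoplasmic background
#'
#' The signal intensity of each tubule is the mean of the signal channel
#' over a band of width \code{profile_width_px} around the tubule skeleton;
#' a tubule is positive when that intensity is at least
#' \code{positive_fold_threshold} times the cytoplasmic background
#' (inclusive at the boundary: "at least 50 percent above background" means
#' signal >= 1.5 x background). The per-cell positive fraction treats each
#' cell as one biological data point; cells with zero tubules get a missing
#' fraction.
#'
#' @param tubules List of tubules from \code{\link{detect_tubules}}.
#' @param signal_plane Numeric matrix (the marker channel).
#' @param background Cytoplasmic background intensity (> 0), or a named
#'   vector per cell.
#' @param config An \code{\link{analysis_config}}.
#' @param cell_ids Optional character vector, one per tubule (default: one
#'   cell \code{"cell1"}).
#' @return List with \code{calls} (data frame: cell_id, tubule_id,
#'   length_px, signal_intensity, cytoplasmic_background, positive) and
#'   \code{cell_fractions} (data frame: cell_id, n_tubules, n_positive,
#'   fraction_positive).
#' @export
classify_tubules <- function(tubules, signal_plane, background,
                             config = analysis_config(), cell_ids = NULL) {
  if (any(background <= 0)) stop("background must be > 0", call. = FALSE)
  n <- length(tubules)
  if (is.null(cell_ids)) cell_ids <- rep("cell1", n)
  if (length(cell_ids) != n)
    stop("cell_ids must have one entry per tubule", call. = FALSE)
  bg_of <- function(cid) {
    if (length(background) == 1L) return(unname(background))
    b <- background[[cid]]
    if (is.null(b)) stop("no background for cell ", cid, call. = FALSE)
    b
  }
  half <- (config$profile_width_px - 1L) %/% 2L
  calls <- data.frame(cell_id = character(), tubule_id = integer(),
                      length_px = numeric(), signal_intensity = numeric(),
                      cytoplasmic_background = numeric(), positive = logical())
  for (i in seq_len(n)) {
    tb <- tubules[[i]]
    band <- matrix(FALSE, nrow(signal_plane), ncol(signal_plane))
    band[tb$skeleton_px + 1L] <- TRUE
    if (half > 0) {
      brush <- EBImage::makeBrush(2L * half + 1L, shape = "box")
      band <- EBImage::imageData(EBImage::dilate(EBImage::Image(band * 1),
                                                 brush)) > 0
    }
    sig <- mean(signal_plane[band])
    bg <- bg_of(cell_ids[i])
    calls <- rbind(calls, data.frame(
      cell_id = cell_ids[i], tubule_id = tb$tubule_id,
      length_px = tb$length_px, signal_intensity = sig,
      cytoplasmic_background = bg,
      positive = sig >= config$positive_fold_threshold * bg))
  }
  cells <- unique(cell_ids)
  fr <- data.frame(cell_id = cells,
                   n_tubules = vapply(cells, function(cid)
                     sum(calls$cell_id == cid), 1L),
                   n_positive = vapply(cells, function(cid)
                     sum(calls$positive[calls$cell_id == cid]), 1L))
  fr$fraction_positive <- ifelse(fr$n_tubules > 0,
                                 fr$n_positive / fr$n_tubules, NA_real_)
  list(calls = calls, cell_fractions = fr)
}

# ---- profile alignment and fold-change normalization -----------------------

#' Align profiles on their reference peak and normalize to fold-change
#'
#' Each profile is linearly shifted (no wrapping; vacated samples are
#' missing) so that the position of its highest reference-channel
#' fluorescence sits at the common centre index, \code{floor((L - 1) / 2)}
#' for grid length L (ties broken by first occurrence). The per-profile,
#' per-channel cytoplasmic background is the mean of samples outside a
#' \code{profile_exclusion_window_px}-wide window centred on the peak; every
#' channel is divided by its own background, so values read as fold-change
#' over cytoplasm. Across profiles, the per-position mean and t-based 95
#' percent confidence interval are returned.
#'
#' @param profiles List of \code{\link{line_profile}} objects.
#' @param reference_channel Channel used for peak alignment.
#' @param config An \code{\link{analysis_config}}.
#' @return Object of class \code{aligned_profiles}: \code{positions}
#'   (0-based), \code{center_index}, \code{channel_names}, matrices
#'   \code{mean}, \code{ci_half_width}, \code{n} (positions x channels),
#'   and \code{profiles}, the aligned normalized inputs.
#' @export
align_and_normalize_profiles <- function(profiles, reference_channel = 1L,
                                         config = analysis_config()) {
  if (!length(profiles)) stop("need at least one profile", call. = FALSE)
  W <- config$profile_exclusion_window_px
  halfw <- (W - 1L) %/% 2L
  L <- max(vapply(profiles, function(p) nrow(p$values), 1L))
  center <- (L - 1L) %/% 2L          # 0-based
  nch <- ncol(profiles[[1]]$values)
  chn <- profiles[[1]]$channel_names
  aligned <- vector("list", length(profiles))
  arr <- array(NA_real_, dim = c(L, nch, length(profiles)))
  for (i in seq_along(profiles)) {
    pr <- profiles[[i]]
    ni <- nrow(pr$values)
    if (ni < W + 2L)
      stop("profile ", i, " (", ni, " samples) shorter than exclusion ",
           "window + 2", call. = FALSE)
    ref <- profile_channel(pr, reference_channel)
    if (all(is.na(ref))) stop("profile ", i, ": reference channel all missing",
                              call. = FALSE)
    peak <- which.max(ref)           # first occurrence on ties
    offset <- center - (peak - 1L)
    shifted <- matrix(NA_real_, L, nch)
    src <- seq_len(ni)
    dst <- src + offset
    keep <- dst >= 1L & dst <= L
    shifted[dst[keep], ] <- pr$values[src[keep], ]
    out_win <- abs(seq_len(L) - 1L - center) > halfw
    bg <- colMeans(shifted[out_win, , drop = FALSE], na.rm = TRUE)
    if (any(!is.finite(bg)) || any(bg == 0))
      stop("profile ", i, ": off-window background undefined or zero",
           call. = FALSE)
    normed <- sweep(shifted, 2, bg, "/")
    arr[, , i] <- normed
    aligned[[i]] <- line_profile(normed, width_px = pr$width_px,
                                 channel_names = chn,
                                 vesicle_id = pr$vesicle_id,
                                 diameter_um = pr$diameter_um,
                                 alignment_offset = offset,
                                 background = bg)
  }
  nmat <- apply(!is.na(arr), c(1, 2), sum)
  mmat <- apply(arr, c(1, 2), function(v) mean(v, na.rm = TRUE))
  mmat[nmat == 0] <- NA_real_
  sdm <- apply(arr, c(1, 2), function(v) stats::sd(v, na.rm = TRUE))
  ci <- matrix(NA_real_, L, nch)
  has <- nmat >= 2
  ci[has] <- stats::qt(0.975, nmat[has] - 1) * sdm[has] / sqrt(nmat[has])
  colnames(mmat) <- colnames(ci) <- colnames(nmat) <- chn
  structure(list(positions = seq_len(L) - 1L, center_index = center,
                 channel_names = chn, mean = mmat, ci_half_width = ci,
                 n = nmat, profiles = aligned),
            class = "aligned_profiles")
}

#' Export an aligned-profile aggregate as CSV
#'
#' Columns: \code{position, channel, mean, ci_half_width, n}.
#'
#' @param aggregate An \code{aligned_profiles} object.
#' @param path Output CSV path.
#' @export
write_aligned_profiles <- function(aggregate, path) {
  stopifnot(inherits(aggregate, "aligned_profiles"))
  rows <- do.call(rbind, lapply(seq_along(aggregate$channel_names),
    function(ci) data.frame(position = aggregate$positions,
                            channel = aggregate$channel_names[ci],
                            mean = aggregate$mean[, ci],
                            ci_half_width = aggregate$ci_half_width[, ci],
                            n = aggregate$n[, ci])))
  write.csv(rows, path, row.names = FALSE, na = "NA")
  invisible(path)
}
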