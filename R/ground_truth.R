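# Ground-truth construction from contour masks.
#
# Coordinate conventions used throughout: 0-based pixel indices, top-left
# origin, y down.  A pixel at (row r, col c) occupies the half-open extent
# [r, r+1) x [c, c+1), so the tight box around a mask spans
# [min_row, max_row + 1) x [min_col, max_col + 1) in pixel units and is
# normalized by the image size.

#' Tight bounding box of a binary mask
#'
#' The least axis-aligned rectangle containing every true pixel of the
#' mask, in normalized coordinates.  Box edges follow the half-open pixel
#' extent convention: `x1 = min_col / cols`, `x2 = (max_col + 1) / cols`,
#' and analogously for rows, so the box covers each true pixel's full
#' extent.
#'
#' @param mask logical (or 0/1) matrix; must contain at least one true
#'   pixel.
#' @param rows,cols image dimensions; default to `dim(mask)`.
#' @return A [BoundingBox-class].
#' @examples
#' m <- matrix(FALSE, 100, 100); m[11:20, 21:40] <- TRUE
#' corners(bboxFromMask(m))  # (0.20, 0.10, 0.40, 0.20)
#' @export
bboxFromMask <- function(mask, rows = nrow(mask), cols = ncol(mask)) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    stop("empty mask: no LV annotation present")
  r0 <- min(idx[, 1L]) - 1L; r1 <- max(idx[, 1L])  # half-open, 0-based
  c0 <- min(idx[, 2L]) - 1L; c1 <- max(idx[, 2L])
  boundingBox(c0 / cols, r0 / rows, c1 / cols, r1 / rows)
}

#' Blood-pool centre from the endocardial mask
#'
#' The reference blood-pool centre is the midpoint of the tight bounding
#' box around the endocardial mask (not the mask centroid; see
#' `centre = "centroid"` for the alternative), in continuous 0-based
#' pixel coordinates.
#'
#' @param endocardial logical (or 0/1) matrix.
#' @param centre `"box"` (default) for the tight-box midpoint,
#'   `"centroid"` for the pixel centroid.
#' @return Numeric `(row, col)` in pixels.
#' @examples
#' m <- matrix(FALSE, 100, 100); m[11:20, 21:40] <- TRUE
#' bpCentre(m)  # (15, 30)
#' @export
bpCentre <- function(endocardial, centre = c("box", "centroid")) {
  centre <- match.arg(centre)
  idx <- which(endocardial != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty endocardial mask")
  if (centre == "box") {
    r <- (min(idx[, 1L]) - 1 + max(idx[, 1L])) / 2
    c <- (min(idx[, 2L]) - 1 + max(idx[, 2L])) / 2
  } else {
    # centroid of pixel centres (pixel (i,j) has centre (i-1+0.5, j-1+0.5));
    # the 0.5 offsets cancel against the half-open box convention above
    r <- mean(idx[, 1L]) - 0.5
    c <- mean(idx[, 2L]) - 0.5
  }
  c(row = r, col = c)
}

#' Equiangular myocardial segmentation
#'
#' Assigns every myocardial pixel (epicardial minus endocardial mask) to
#' one of `nSegments` angular sectors of width `2*pi/nSegments` around
#' the blood-pool centre, as in the AHA segmental model: six segments in
#' basal and middle slices, four in the apical slice.  Sector 1 starts at
#' `referenceAngle` and numbering proceeds clockwise on screen (the
#' default reference is the anterior, i.e. upward, direction).
#'
#' @param masks a [ContourMasks-class].
#' @param nSegments number of sectors (>= 1).
#' @param referenceAngle start angle in radians, measured clockwise from
#'   the upward image direction.
#' @return Integer matrix: 0 outside the myocardium, 1..`nSegments`
#'   inside.
#' @examples
#' p <- generatePhantom(phantomSpec("middle", imageRows = 64), seed = 1)
#' table(equiangularSegments(contourMasksOf(p), 6))
#' @export
equiangularSegments <- function(masks, nSegments, referenceAngle = 0) {
  stopifnot(is(masks, "ContourMasks"))
  if (nSegments < 1L) stop("nSegments must be >= 1")
  myo <- masks@epicardial & !masks@endocardial
  if (!any(myo)) stop("empty myocardium")
  ctr <- bpCentre(masks@endocardial)
  idx <- which(myo, arr.ind = TRUE)
  dr <- idx[, 1L] - 1 - ctr[["row"]]
  dc <- idx[, 2L] - 1 - ctr[["col"]]
  # theta = 0 points up (anterior), increasing clockwise on screen
  # (up -> right -> down -> left); y grows downward in image coords.
  theta <- atan2(dc, -dr) %% (2 * pi)
  sector <- floor(((theta - referenceAngle) %% (2 * pi)) /
                    (2 * pi / nSegments)) + 1L
  sector[sector > nSegments] <- 1L  # guard against floating-point wrap
  labels <- matrix(0L, nrow(myo), ncol(myo))
  labels[idx] <- as.integer(sector)
  labels
}

#' Mono-exponential T2* fit
#'
#' Fits `S(TE) = S0 * exp(-TE / T2*)` to per-segment mean signals by
#' nonlinear least squares, initialized from a signal-weighted log-linear
#' regression (weights `S^2`, under which log-domain least squares
#' matches the linear-domain objective to first order).  The fit is exact
#' on noiseless exponential input.  Non-decaying (degenerate) input is
#' returned flagged rather than as an error.
#'
#' @param meanSignals positive numeric vector of mean signals.
#' @param tes echo times (ms), same length, at least 2.
#' @return A list with `s0`, `t2star` (ms) and `converged` (logical;
#'   `FALSE` flags a degenerate or non-converged fit whose `t2star` is
#'   the log-linear estimate, possibly `Inf` for non-decaying input).
#' @examples
#' tes <- echoTimes(10, 2.0, 2.26)
#' fitT2Star(100 * exp(-tes / 20), tes)
#' @export
fitT2Star <- function(meanSignals, tes) {
  s <- as.numeric(meanSignals); te <- as.numeric(tes)
  if (length(s) != length(te) || length(s) < 2L)
    stop("need >= 2 (signal, TE) pairs of equal length")
  if (any(!is.finite(s)) || any(s <= 0))
    stop("signals must be positive and finite")
  # weighted log-linear initializer: log S = log S0 - TE / T2*
  fit0 <- stats::lm.wfit(cbind(1, te), log(s), w = s^2)
  slope <- unname(fit0$coefficients[2L])
  s0Init <- unname(exp(fit0$coefficients[1L]))
  if (!is.finite(slope) || slope >= -1e-12) {
    # no measurable decay: flag, report the (possibly infinite) estimate
    return(list(s0 = s0Init,
                t2star = if (slope == 0 || slope > 0) Inf else -1 / slope,
                converged = FALSE))
  }
  t2Init <- -1 / slope
  fit <- tryCatch(
    minpack.lm::nlsLM(s ~ s0 * exp(-te / t2), start = list(s0 = s0Init, t2 = t2Init),
                      lower = c(0, 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(s0 = s0Init, t2star = t2Init, converged = FALSE))
  cf <- stats::coef(fit)
  list(s0 = unname(cf[["s0"]]), t2star = unname(cf[["t2"]]), converged = TRUE)
}

#' Segmental T2* analysis of a multi-echo stack
#'
#' Runs the full reference-standard pipeline on one slice: equiangular
#' segmentation of the myocardium, per-segment mean signal across echoes,
#' and a mono-exponential fit per segment.
#'
#' @param sequence an [ImageSequence-class] with echo-time metadata.
#' @param masks a [ContourMasks-class].
#' @param nSegments sectors (6 basal/middle, 4 apical).
#' @param referenceAngle passed to [equiangularSegments()].
#' @return A list with `labels` (integer matrix), `segmentT2` (numeric,
#'   ms), `converged` (logical vector) and `segmentS0`.
#' @export
segmentalT2Star <- function(sequence, masks, nSegments, referenceAngle = 0) {
  stopifnot(is(sequence, "ImageSequence"))
  tes <- echoTimes(sequence)
  if (anyNA(tes)) stop("sequence carries no echo-time metadata")
  labels <- equiangularSegments(masks, nSegments, referenceAngle)
  segT2 <- segS0 <- numeric(nSegments); conv <- logical(nSegments)
  for (g in seq_len(nSegments)) {
    sel <- labels == g
    if (!any(sel)) stop(sprintf("segment %d is empty", g))
    means <- apply(sequence@data, 3L, function(frame) mean(frame[sel]))
    f <- fitT2Star(pmax(means, .Machine$double.eps), tes)
    segT2[g] <- f$t2star; segS0[g] <- f$s0; conv[g] <- f$converged
  }
  list(labels = labels, segmentT2 = segT2, segmentS0 = segS0, converged = conv)
}

#' Global heart T2* from the 16 AHA segmental values
#'
#' The global value is the arithmetic mean of all 16 segmental values of
#' the standard AHA model (6 basal + 6 middle + 4 apical); any other
#' count is rejected.
#'
#' @param segmentValues numeric vector of exactly 16 segmental T2* values
#'   (ms).
#' @return Numeric scalar, ms.
#' @examples
#' globalT2Star(rep(30, 16))
#' @export
globalT2Star <- function(segmentValues) {
  v <- as.numeric(segmentValues)
  if (length(v) != 16L)
    stop(sprintf("expected 16 segmental values (6+6+4), got %d", length(v)))
  mean(v)
}
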