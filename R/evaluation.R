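# Detection metrics and their per-slice aggregation: IoU, DICE,
# centre-point absolute and fractional errors, and the correct
# identification rate (CIR).

interArea <- function(a, b) {
  pmax(0, pmin(a[3L], b[3L]) - pmax(a[1L], b[1L])) *
    pmax(0, pmin(a[4L], b[4L]) - pmax(a[2L], b[2L]))
}

boxArea <- function(a) pmax(0, a[3L] - a[1L]) * pmax(0, a[4L] - a[2L])

#' Intersection over union of two boxes
#'
#' Continuous-area Jaccard index
#' `|a intersect b| / |a union b|`, in `[0, 1]`.  Corners may be in any
#' consistent units.
#'
#' @param a,b boxes: [BoundingBox-class] or numeric `(x1, y1, x2, y2)`.
#' @return Scalar fraction.
#' @examples
#' boxIoU(c(0, 0, 2, 2), c(1, 1, 3, 3))  # 1/7
#' @export
boxIoU <- function(a, b) {
  a <- asCorners(a); b <- asCorners(b)
  I <- interArea(a, b)
  U <- boxArea(a) + boxArea(b) - I
  if (U <= 0) return(0)
  I / U
}

#' DICE overlap of two boxes
#'
#' `2 |a intersect b| / (|a| + |b|)`; for any two regions this equals
#' `2 IoU / (1 + IoU)`.
#'
#' @inheritParams boxIoU
#' @return Scalar fraction in `[0, 1]`.
#' @examples
#' boxDice(c(0, 0, 2, 2), c(1, 1, 3, 3))  # 0.25
#' @export
boxDice <- function(a, b) {
  a <- asCorners(a); b <- asCorners(b)
  den <- boxArea(a) + boxArea(b)
  if (den <= 0) return(0)
  2 * interArea(a, b) / den
}

boxCentre <- function(a) c((a[1L] + a[3L]) / 2, (a[2L] + a[4L]) / 2)

#' Centre-point errors of a predicted box
#'
#' The absolute error is the Euclidean distance in pixels between the
#' predicted and ground-truth box centres (normalized coordinates scaled
#' by the image size).  The fractional errors divide it by the radius of
#' the circle with the same area as the epicardial (respectively
#' endocardial) mask, `sqrt(area / pi)`.
#'
#' @param pred,gt boxes in normalized coordinates.
#' @param masks a [ContourMasks-class] (for the mask areas).
#' @param rows,cols image size in pixels; default from the masks.
#' @return Named numeric: `epsCpA` (pixels), `epsCpEpi`, `epsCpEndo`
#'   (fractions).
#' @export
centreErrors <- function(pred, gt, masks,
                         rows = nrow(epicardial(masks)),
                         cols = ncol(epicardial(masks))) {
  stopifnot(is(masks, "ContourMasks"))
  areaEpi <- sum(masks@epicardial); areaEndo <- sum(masks@endocardial)
  if (areaEpi == 0 || areaEndo == 0) stop("empty mask")
  cp <- boxCentre(asCorners(pred)); cg <- boxCentre(asCorners(gt))
  epsA <- sqrt(((cp[1L] - cg[1L]) * cols)^2 + ((cp[2L] - cg[2L]) * rows)^2)
  c(epsCpA = epsA,
    epsCpEpi = epsA / sqrt(areaEpi / pi),
    epsCpEndo = epsA / sqrt(areaEndo / pi))
}

#' Does the predicted box centre fall inside the endocardial mask?
#'
#' The continuous normalized centre is mapped to the pixel that contains
#' it (floor of the pixel coordinates) and looked up in the mask; a
#' centre on a boundary pixel counts as a hit, and a centre outside the
#' image is a miss, not an error.
#'
#' @param pred predicted box, normalized coordinates.
#' @param endocardial logical (or 0/1) endocardial mask.
#' @param rows,cols image size; default from the mask.
#' @return Logical flag.
#' @export
cirHit <- function(pred, endocardial, rows = nrow(endocardial),
                   cols = ncol(endocardial)) {
  if (!any(endocardial != 0)) stop("empty endocardial mask")
  ctr <- boxCentre(asCorners(pred))
  col0 <- floor(ctr[1L] * cols); row0 <- floor(ctr[2L] * rows)
  if (row0 < 0 || row0 >= rows || col0 < 0 || col0 >= cols) return(FALSE)
  endocardial[row0 + 1L, col0 + 1L] != 0
}

#' Per-image detection metrics
#'
#' Computes one metrics record per image: IoU, DICE, centre-point
#' absolute error (pixels), epicardial/endocardial fractional errors and
#' the CIR hit flag.  Masks are optional; without them the mask-based
#' columns are `NA`.
#'
#' @param predBoxes,gtBoxes lists of boxes (or n x 4 matrices),
#'   normalized coordinates.
#' @param sliceTypes character vector of slice labels
#'   (basal/middle/apical).
#' @param masks optional list of [ContourMasks-class].
#' @param imageIds optional character ids.
#' @param rows,cols image size in pixels (needed when `masks` is NULL
#'   only for `epsCpA`; defaults to mask dimensions otherwise).
#' @return data.frame with columns `image_id`, `slice_type`, `iou`,
#'   `dice`, `eps_cp_a`, `eps_cp_epi`, `eps_cp_endo`, `cir_hit`.
#' @export
evaluateDetections <- function(predBoxes, gtBoxes, sliceTypes,
                               masks = NULL, imageIds = NULL,
                               rows = NULL, cols = NULL) {
  toMat <- function(x) if (is.matrix(x)) x else do.call(rbind, lapply(x, asCorners))
  P <- toMat(predBoxes); G <- toMat(gtBoxes)
  n <- nrow(P)
  stopifnot(nrow(G) == n, length(sliceTypes) == n)
  if (is.null(imageIds)) imageIds <- sprintf("img%05d", seq_len(n))
  rec <- data.frame(image_id = imageIds, slice_type = sliceTypes,
                    iou = NA_real_, dice = NA_real_, eps_cp_a = NA_real_,
                    eps_cp_epi = NA_real_, eps_cp_endo = NA_real_,
                    cir_hit = NA, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    rec$iou[i] <- boxIoU(P[i, ], G[i, ])
    rec$dice[i] <- boxDice(P[i, ], G[i, ])
    if (!is.null(masks)) {
      m <- masks[[i]]
      ce <- centreErrors(P[i, ], G[i, ], m)
      rec$eps_cp_a[i] <- ce[["epsCpA"]]
      rec$eps_cp_epi[i] <- ce[["epsCpEpi"]]
      rec$eps_cp_endo[i] <- ce[["epsCpEndo"]]
      rec$cir_hit[i] <- cirHit(P[i, ], endocardial(m))
    } else if (!is.null(rows) && !is.null(cols)) {
      cp <- boxCentre(P[i, ]); cg <- boxCentre(G[i, ])
      rec$eps_cp_a[i] <- sqrt(((cp[1L] - cg[1L]) * cols)^2 +
                                ((cp[2L] - cg[2L]) * rows)^2)
    }
  }
  rec
}

#' Aggregate per-image metrics by slice type
#'
#' Mean and standard deviation of every metric per slice type plus a
#' pooled Global row over all records (not a mean of the slice rows).
#' CIR is reported as the hit rate, the mean of the hit flags.
#'
#' @param records data.frame from [evaluateDetections()].
#' @return data.frame with one row per slice type present (ordered
#'   basal, middle, apical) plus `Global`; columns `n` and
#'   `<metric>_mean` / `<metric>_sd` for iou, dice, eps_cp_a,
#'   eps_cp_epi, eps_cp_endo and cir.
#' @export
aggregateMetrics <- function(records) {
  known <- c("basal", "middle", "apical")
  if (nrow(records) == 0L) stop("no records to aggregate")
  bad <- setdiff(unique(records$slice_type), known)
  if (length(bad))
    stop("unknown slice label(s): ", paste(bad, collapse = ", "))
  metrics <- c("iou", "dice", "eps_cp_a", "eps_cp_epi", "eps_cp_endo")
  summarise <- function(df, label) {
    row <- data.frame(slice = label, n = nrow(df), stringsAsFactors = FALSE)
    for (m in metrics) {
      row[[paste0(m, "_mean")]] <- mean(df[[m]])
      row[[paste0(m, "_sd")]] <- stats::sd(df[[m]])
    }
    flags <- as.numeric(df$cir_hit)
    row$cir_mean <- mean(flags)
    row$cir_sd <- stats::sd(flags)
    row
  }
  out <- do.call(rbind, lapply(intersect(known, unique(records$slice_type)),
                               function(sl)
                                 summarise(records[records$slice_type == sl, ,
                                                   drop = FALSE], sl)))
  rbind(out, summarise(records, "Global"))
}
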