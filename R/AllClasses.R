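#' @import methods
NULL

#' Multi-frame short-axis image stack
#'
#' An `ImageSequence` holds one short-axis acquisition as a numeric
#' `rows x cols x frames` array together with the echo time (TE, ms) at
#' which each frame was acquired.  Frames are ordered by acquisition, the
#' array origin is the top-left pixel, and the first array index runs down
#' the rows (y increases downward).
#'
#' @slot data numeric 3-D array, `rows x cols x frames`.
#' @slot echoTimes numeric vector of per-frame echo times in ms (may be
#'   `NA` when the source carries no timing metadata).
#'
#' @seealso [imageSequence()], [selectFrames()], [patchify()]
#' @export
setClass("ImageSequence",
  representation(data = "array", echoTimes = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@data)) != 3L)
      msg <- c(msg, "'data' must be a rows x cols x frames array")
    else if (length(object@echoTimes) != dim(object@data)[3L])
      msg <- c(msg, "length(echoTimes) must equal the number of frames")
    if (anyNA(object@data) || !all(is.finite(object@data)))
      msg <- c(msg, "'data' must be finite")
    if (length(msg)) msg else TRUE
  })

#' Construct an ImageSequence
#'
#' @param data numeric `rows x cols x frames` array (a matrix is promoted
#'   to a single-frame stack).
#' @param echoTimes numeric vector of echo times (ms), one per frame;
#'   defaults to `NA` for every frame.
#' @return An [ImageSequence-class] object.
#' @examples
#' x <- imageSequence(array(0, c(8, 8, 3)), echoTimes = c(2, 11.04, 20.08))
#' dim(x)
#' @export
imageSequence <- function(data, echoTimes = rep(NA_real_, dim(data)[3L])) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  new("ImageSequence", data = data, echoTimes = as.numeric(echoTimes))
}

#' Paired epicardial/endocardial contour masks
#'
#' Binary masks tracing the outer (epicardial) and inner (endocardial)
#' myocardial boundaries on one slice.  The endocardial mask must be
#' contained, pixel-wise, in the epicardial mask; the myocardium is their
#' set difference and the blood pool is the endocardial region.
#'
#' @slot epicardial logical matrix.
#' @slot endocardial logical matrix of the same dimensions.
#' @seealso [contourMasks()], [bboxFromMask()], [equiangularSegments()]
#' @export
setClass("ContourMasks",
  representation(epicardial = "matrix", endocardial = "matrix"),
  validity = function(object) {
    msg <- character()
    if (!is.logical(object@epicardial) || !is.logical(object@endocardial))
      msg <- c(msg, "masks must be logical matrices")
    else {
      if (!identical(dim(object@epicardial), dim(object@endocardial)))
        msg <- c(msg, "mask dimensions differ")
      else if (any(object@endocardial & !object@epicardial))
        msg <- c(msg, "endocardial mask must be contained in the epicardial mask")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a ContourMasks object
#'
#' @param epicardial,endocardial logical (or 0/1 numeric) matrices of equal
#'   size; `endocardial` must be contained in `epicardial`.
#' @return A [ContourMasks-class] object.
#' @export
contourMasks <- function(epicardial, endocardial) {
  toLogical <- function(m) {
    if (!is.logical(m)) { m2 <- m != 0; dim(m2) <- dim(m); m2 } else m
  }
  new("ContourMasks", epicardial = toLogical(epicardial),
      endocardial = toLogical(endocardial))
}

#' Normalized axis-aligned bounding box
#'
#' Box corners in normalized image coordinates: `x` is the column fraction,
#' `y` the row fraction, origin at the top-left corner with y increasing
#' downward.  `(x1, y1)` is the top-left and `(x2, y2)` the bottom-right
#' corner; a valid box has `0 <= x1 < x2 <= 1` and `0 <= y1 < y2 <= 1`.
#'
#' @slot x1,y1,x2,y2 numeric scalars.
#' @seealso [boundingBox()], [boxIoU()], [boxDice()]
#' @export
setClass("BoundingBox",
  representation(x1 = "numeric", y1 = "numeric", x2 = "numeric", y2 = "numeric"),
  validity = function(object) {
    v <- c(object@x1, object@y1, object@x2, object@y2)
    if (length(v) != 4L || anyNA(v)) return("corners must be 4 finite scalars")
    if (object@x1 < 0 || object@y1 < 0 || object@x2 > 1 || object@y2 > 1)
      return("corners must lie in [0, 1]")
    if (object@x1 >= object@x2 || object@y1 >= object@y2)
      return("need x1 < x2 and y1 < y2")
    TRUE
  })

#' Construct a BoundingBox
#'
#' @param x1,y1 top-left corner (normalized column/row fractions).
#' @param x2,y2 bottom-right corner.
#' @return A [BoundingBox-class] object.
#' @examples
#' boundingBox(0.3, 0.3, 0.6, 0.7)
#' @export
boundingBox <- function(x1, y1, x2, y2)
  new("BoundingBox", x1 = as.numeric(x1), y1 = as.numeric(y1),
      x2 = as.numeric(x2), y2 = as.numeric(y2))

#' Synthetic short-axis phantom specification
#'
#' Parameters of the synthetic multi-echo short-axis generator: image
#' geometry, echo-train timing, slice-dependent left-ventricle size
#' ranges, tissue-wise mono-exponential relaxation constants, coil
#' shading, confounding structures and noise.  See [phantomSpec()] for
#' defaults and units.
#'
#' @slot imageRows,imageCols pixel counts.
#' @slot nEchoes number of echoes (frames).
#' @slot te1 first echo time, ms.
#' @slot teSpacing echo spacing, ms.
#' @slot sliceType one of `"basal"`, `"middle"`, `"apical"`.
#' @slot epiRadiusRange,endoRadiusRange semi-axis ranges in pixels.
#' @slot centreJitter maximum LV centre offset from the anchor, pixels.
#' @slot centreAnchor anchor (row, col) for LV placement, pixels.
#' @slot tissueRelaxation named list `tissue -> c(s0, t2)` with signal
#'   amplitude (arbitrary units) and decay constant (ms) for
#'   myocardium, blood, liver, chest_wall, lung and background.  A
#'   myocardium entry with `t2 = NA` means "draw per sample" from
#'   `myoT2Range`.
#' @slot myoT2Range range (ms) from which a per-sample myocardial decay
#'   constant is drawn when not fixed.
#' @slot noiseSigma additive Gaussian noise SD, arbitrary units.
#' @slot coilGradient fractional intensity slope of the multiplicative
#'   coil-sensitivity shading across the field (0 disables it).
#' @slot confounderRange min/max count of bright elliptical confounders.
#' @slot seed integer default seed for [generatePhantom()].
#' @export
setClass("PhantomSpec",
  representation(imageRows = "integer", imageCols = "integer",
                 nEchoes = "integer", te1 = "numeric", teSpacing = "numeric",
                 sliceType = "character",
                 epiRadiusRange = "numeric", endoRadiusRange = "numeric",
                 centreJitter = "numeric", centreAnchor = "numeric",
                 tissueRelaxation = "list", myoT2Range = "numeric",
                 noiseSigma = "numeric", coilGradient = "numeric",
                 confounderRange = "integer", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nEchoes < 2L) msg <- c(msg, "nEchoes must be >= 2")
    if (object@te1 <= 0 || object@teSpacing <= 0)
      msg <- c(msg, "te1 and teSpacing must be positive")
    if (!object@sliceType %in% c("basal", "middle", "apical"))
      msg <- c(msg, "sliceType must be basal, middle or apical")
    if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
    if (max(object@endoRadiusRange) >= min(object@epiRadiusRange) &&
        object@endoRadiusRange[2L] >= object@epiRadiusRange[2L])
      msg <- c(msg, "endoRadiusRange must sit below epiRadiusRange")
    tr <- object@tissueRelaxation
    need <- c("myocardium", "blood", "liver", "chest_wall", "lung", "background")
    if (!all(need %in% names(tr)))
      msg <- c(msg, paste("tissueRelaxation must name:", paste(need, collapse = ", ")))
    else {
      t2s <- vapply(tr, function(v) v[["t2"]], numeric(1))
      if (any(!is.na(t2s) & t2s <= 0)) msg <- c(msg, "all decay constants must be > 0")
    }
    if (length(msg)) msg else TRUE
  })

#' One generated phantom study
#'
#' Container for a single simulated short-axis acquisition: the multi-echo
#' stack, its ground-truth contour masks, the tight epicardial bounding
#' box, the slice label and the tissue decay constants that generated it.
#'
#' @slot sequence an [ImageSequence-class].
#' @slot masks a [ContourMasks-class].
#' @slot gtBox a [BoundingBox-class]; always `bboxFromMask()` of the
#'   epicardial mask.
#' @slot sliceType slice label.
#' @slot segmentT2 per-segment true decay constants (ms), 6 for
#'   basal/middle slices and 4 for apical.
#' @slot myocardialT2 the myocardial decay constant used (ms).
#' @export
setClass("PhantomSample",
  representation(sequence = "ImageSequence", masks = "ContourMasks",
                 gtBox = "BoundingBox", sliceType = "character",
                 segmentT2 = "numeric", myocardialT2 = "numeric"))

#' Vision-Transformer detector configuration
#'
#' Architecture hyper-parameters of the bounding-box regression ViT:
#' input geometry, patch size, embedding width, attention heads, encoder
#' depth and the two MLP stacks.  See [vitConfig()] for the reference
#' configuration.
#'
#' @slot rows,cols,frames input stack dimensions.
#' @slot patchSize patch edge length P (pixels); rows and cols must be
#'   divisible by P, giving `N = rows * cols / P^2` patches.
#' @slot embedDim token width D; must be divisible by `nHeads`.
#' @slot nHeads attention heads per MHSA layer.
#' @slot nBlocks number of transformer encoder blocks.
#' @slot encoderMlpUnits widths of the encoder MLP; the last entry must
#'   equal `embedDim` so the residual connection is well formed.
#' @slot headMlpUnits widths of the regression head MLP (a final linear
#'   4-unit layer is always appended).
#' @slot encoderDropout,headDropout dropout rates in [0, 1).
#' @slot scaleConvention `"paper"` divides attention logits by
#'   `sqrt(dHead / nHeads)` inside MHSA, `"per_head"` by the conventional
#'   `sqrt(dHead)` (where `dHead = embedDim / nHeads`).
#' @slot positional `"learned"` (per-index table) or `"sinusoidal"`.
#' @export
setClass("ViTConfig",
  representation(rows = "integer", cols = "integer", frames = "integer",
                 patchSize = "integer", embedDim = "integer",
                 nHeads = "integer", nBlocks = "integer",
                 encoderMlpUnits = "integer", headMlpUnits = "integer",
                 encoderDropout = "numeric", headDropout = "numeric",
                 scaleConvention = "character", positional = "character"),
  validity = function(object) {
    msg <- character()
    if (object@rows %% object@patchSize != 0L || object@cols %% object@patchSize != 0L)
      msg <- c(msg, "rows and cols must be divisible by patchSize")
    if (object@embedDim %% object@nHeads != 0L)
      msg <- c(msg, "embedDim must be divisible by nHeads")
    if (object@encoderDropout < 0 || object@encoderDropout >= 1 ||
        object@headDropout < 0 || object@headDropout >= 1)
      msg <- c(msg, "dropout rates must lie in [0, 1)")
    if (length(object@encoderMlpUnits) < 1L ||
        object@encoderMlpUnits[length(object@encoderMlpUnits)] != object@embedDim)
      msg <- c(msg, "last encoder MLP width must equal embedDim")
    if (!object@scaleConvention %in% c("paper", "per_head"))
      msg <- c(msg, "scaleConvention must be 'paper' or 'per_head'")
    if (!object@positional %in% c("learned", "sinusoidal"))
      msg <- c(msg, "positional must be 'learned' or 'sinusoidal'")
    if (length(msg)) msg else TRUE
  })

#' A ViT detector with its parameters
#'
#' Bundles a [ViTConfig-class] with the model parameters (a named list of
#' numeric matrices/vectors).  Create with [vitModel()]; run with
#' [predictBox()]; train with [trainDetector()].
#'
#' @slot config a [ViTConfig-class].
#' @slot params named list of parameter arrays.
#' @export
setClass("ViTModel",
  representation(config = "ViTConfig", params = "list"))

#' Subject-grouped k-fold split plan
#'
#' Per fold, disjoint train/validation/test subject-id sets.  All slices
#' of a subject share the subject's partition, test partitions are
#' disjoint across folds and their union covers every subject.
#'
#' @slot k number of folds.
#' @slot subjects all subject ids.
#' @slot folds list of `k` lists, each with `train`, `validation`,
#'   `test` character vectors of subject ids.
#' @export
setClass("FoldPlan",
  representation(k = "integer", subjects = "character", folds = "list"),
  validity = function(object) {
    if (length(object@folds) != object@k) return("length(folds) != k")
    testAll <- character()
    for (f in object@folds) {
      if (!all(c("train", "validation", "test") %in% names(f)))
        return("each fold needs train/validation/test")
      ids <- c(f$train, f$validation, f$test)
      if (anyDuplicated(ids)) return("a subject appears in two partitions of one fold")
      if (!setequal(ids, object@subjects)) return("fold does not cover all subjects")
      testAll <- c(testAll, f$test)
    }
    if (anyDuplicated(testAll)) return("test partitions overlap across folds")
    if (!setequal(testAll, object@subjects)) return("test partitions do not cover all subjects")
    TRUE
  })

#' Detector training configuration
#'
#' @slot batchSize mini-batch size.
#' @slot maxEpochs epoch cap (no early stopping; the best-validation
#'   checkpoint is retained).
#' @slot initialLr initial Adam learning rate.
#' @slot decayRate,decaySteps exponential learning-rate schedule
#'   `lr(t) = initialLr * decayRate^(t / decaySteps)` with `t` the
#'   optimizer step.
#' @slot shiftRange augmentation shift range in pixels (`0` disables).
#' @slot seed integer RNG seed for shuffling, dropout and augmentation.
#' @export
setClass("TrainConfig",
  representation(batchSize = "integer", maxEpochs = "integer",
                 initialLr = "numeric", decayRate = "numeric",
                 decaySteps = "numeric", shiftRange = "integer",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
    if (object@shiftRange < 0L) msg <- c(msg, "shiftRange must be >= 0")
    if (object@initialLr <= 0) msg <- c(msg, "initialLr must be > 0")
    if (object@decayRate <= 0 || object@decayRate > 1)
      msg <- c(msg, "decayRate must lie in (0, 1]")
    if (length(msg)) msg else TRUE
  })
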