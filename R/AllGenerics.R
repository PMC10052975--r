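#' Echo times of a stack, or an arithmetic echo-time train
#'
#' Multi-echo relaxometry acquires frames at echo times
#' `TE_k = te1 + (k - 1) * spacing`.  Called on a count, `echoTimes()`
#' builds that train; called on an [ImageSequence-class], it returns the
#' stack's per-frame echo times.
#'
#' @param x an `ImageSequence`, or a single positive integer (the number
#'   of echoes).
#' @param te1 first echo time, ms (must be > 0).
#' @param spacing echo spacing, ms (must be > 0).
#' @param ... unused.
#' @return Numeric vector of echo times in ms, strictly increasing.
#' @examples
#' echoTimes(10, te1 = 2.0, spacing = 2.26)
#' @export
setGeneric("echoTimes", function(x, ...) standardGeneric("echoTimes"))

#' @rdname echoTimes
#' @export
setMethod("echoTimes", "numeric", function(x, te1, spacing, ...) {
  n <- x
  if (length(n) != 1L || is.na(n) || n < 1 || n != round(n))
    stop("number of echoes must be a single positive integer")
  if (te1 <= 0) stop("te1 must be > 0")
  if (spacing <= 0) stop("spacing must be > 0")
  te1 + (seq_len(n) - 1) * spacing
})

#' @rdname echoTimes
#' @export
setMethod("echoTimes", "ImageSequence", function(x, ...) x@echoTimes)

#' Pixel data of an image stack
#' @param x an [ImageSequence-class].
#' @return The underlying `rows x cols x frames` numeric array.
#' @export
setGeneric("imageData", function(x) standardGeneric("imageData"))

#' @rdname imageData
#' @export
setMethod("imageData", "ImageSequence", function(x) x@data)

#' @describeIn ImageSequence-class stack dimensions `(rows, cols, frames)`.
#' @param x an `ImageSequence`.
#' @export
setMethod("dim", "ImageSequence", function(x) dim(x@data))

#' Epicardial / endocardial mask accessors
#' @param x a [ContourMasks-class] or [PhantomSample-class].
#' @return Logical matrix.
#' @export
setGeneric("epicardial", function(x) standardGeneric("epicardial"))

#' @rdname epicardial
#' @export
setGeneric("endocardial", function(x) standardGeneric("endocardial"))

#' @rdname epicardial
#' @export
setMethod("epicardial", "ContourMasks", function(x) x@epicardial)

#' @rdname epicardial
#' @export
setMethod("endocardial", "ContourMasks", function(x) x@endocardial)

#' @rdname epicardial
#' @export
setMethod("epicardial", "PhantomSample", function(x) x@masks@epicardial)

#' @rdname epicardial
#' @export
setMethod("endocardial", "PhantomSample", function(x) x@masks@endocardial)

#' Box corners as a named vector
#' @param x a [BoundingBox-class].
#' @return Named numeric `(x1, y1, x2, y2)`.
#' @export
setGeneric("corners", function(x) standardGeneric("corners"))

#' @rdname corners
#' @export
setMethod("corners", "BoundingBox",
          function(x) c(x1 = x@x1, y1 = x@y1, x2 = x@x2, y2 = x@y2))

#' Phantom sample accessors
#' @param x a [PhantomSample-class].
#' @return `gtBox()`: the ground-truth [BoundingBox-class]; `sliceType()`:
#'   the slice label; `imageSequenceOf()`: the [ImageSequence-class];
#'   `contourMasksOf()`: the [ContourMasks-class].
#' @export
setGeneric("gtBox", function(x) standardGeneric("gtBox"))

#' @rdname gtBox
#' @export
setMethod("gtBox", "PhantomSample", function(x) x@gtBox)

#' @rdname gtBox
#' @export
setGeneric("sliceType", function(x) standardGeneric("sliceType"))

#' @rdname gtBox
#' @export
setMethod("sliceType", "PhantomSample", function(x) x@sliceType)

#' @rdname gtBox
#' @export
setGeneric("imageSequenceOf", function(x) standardGeneric("imageSequenceOf"))

#' @rdname gtBox
#' @export
setMethod("imageSequenceOf", "PhantomSample", function(x) x@sequence)

#' @rdname gtBox
#' @export
setGeneric("contourMasksOf", function(x) standardGeneric("contourMasksOf"))

#' @rdname gtBox
#' @export
setMethod("contourMasksOf", "PhantomSample", function(x) x@masks)

#' Model accessors
#' @param x a [ViTModel-class].
#' @return `modelConfig()`: the [ViTConfig-class]; `modelParams()`: the
#'   named parameter list.
#' @export
setGeneric("modelConfig", function(x) standardGeneric("modelConfig"))

#' @rdname modelConfig
#' @export
setMethod("modelConfig", "ViTModel", function(x) x@config)

#' @rdname modelConfig
#' @export
setGeneric("modelParams", function(x) standardGeneric("modelParams"))

#' @rdname modelConfig
#' @export
setMethod("modelParams", "ViTModel", function(x) x@params)

#' Number of trainable parameters
#'
#' The parameter count is a pure function of the architecture
#' configuration; it is reported by `show()` and pinned in the test
#' suite so refactors cannot silently change the architecture.
#'
#' @param x a [ViTModel-class] or [ViTConfig-class].
#' @return Integer scalar.
#' @export
setGeneric("nParams", function(x) standardGeneric("nParams"))

#' @rdname nParams
#' @export
setMethod("nParams", "ViTModel",
          function(x) sum(vapply(x@params, length, integer(1))))

setMethod("show", "ImageSequence", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageSequence: %d x %d pixels, %d frame(s)\n", d[1], d[2], d[3]))
  te <- object@echoTimes
  if (!all(is.na(te)))
    cat("  echo times (ms):", paste(format(te, trim = TRUE), collapse = ", "), "\n")
})

setMethod("show", "BoundingBox", function(object) {
  cat(sprintf("BoundingBox: (%.4f, %.4f) -- (%.4f, %.4f) [normalized]\n",
              object@x1, object@y1, object@x2, object@y2))
})

setMethod("show", "ContourMasks", function(object) {
  d <- dim(object@epicardial)
  cat(sprintf("ContourMasks: %d x %d; epicardial %d px, endocardial %d px\n",
              d[1], d[2], sum(object@epicardial), sum(object@endocardial)))
})

setMethod("show", "PhantomSample", function(object) {
  d <- dim(object@sequence)
  cat(sprintf("PhantomSample (%s slice): %d x %d x %d, myocardial T2* %.2f ms\n",
              object@sliceType, d[1], d[2], d[3], object@myocardialT2))
  cat(sprintf("  GT box: (%.3f, %.3f) -- (%.3f, %.3f)\n",
              object@gtBox@x1, object@gtBox@y1, object@gtBox@x2, object@gtBox@y2))
})

setMethod("show", "ViTConfig", function(object) {
  n <- (object@rows %/% object@patchSize) * (object@cols %/% object@patchSize)
  cat(sprintf(paste0(
    "ViTConfig: %dx%dx%d input, P=%d (N=%d patches), D=%d, h=%d heads, ",
    "%d encoder block(s)\n"),
    object@rows, object@cols, object@frames, object@patchSize, n,
    object@embedDim, object@nHeads, object@nBlocks))
  cat("  encoder MLP:", paste(object@encoderMlpUnits, collapse = "/"),
      sprintf("(dropout %.2f)", object@encoderDropout), "\n")
  cat("  head MLP:", paste(object@headMlpUnits, collapse = "/"),
      sprintf("-> 4 (dropout %.2f)", object@headDropout), "\n")
})

setMethod("show", "ViTModel", function(object) {
  show(object@config)
  cat(sprintf("  %s trainable parameters\n",
              format(nParams(object), big.mark = ",")))
})

setMethod("show", "FoldPlan", function(object) {
  cat(sprintf("FoldPlan: %d folds over %d subjects\n",
              object@k, length(object@subjects)))
  f1 <- object@folds[[1L]]
  cat(sprintf("  fold sizes (train/val/test): %d/%d/%d subjects\n",
              length(f1$train), length(f1$validation), length(f1$test)))
})

setMethod("show", "TrainConfig", function(object) {
  cat(sprintf(paste0("TrainConfig: batch %d, <=%d epochs, lr %.2g ",
                     "(decay %.2f / %g steps), shift +/-%d px, seed %d\n"),
      object@batchSize, object@maxEpochs, object@initialLr, object@decayRate,
      object@decaySteps, object@shiftRange, object@seed))
})
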