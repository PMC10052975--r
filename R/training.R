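# Training protocol: 1-DICE box loss, on-the-fly shift augmentation,
# subject-grouped stratified k-fold splitting, Adam with exponential
# learning-rate decay, best-validation checkpointing.

asCorners <- function(b) {
  if (is(b, "BoundingBox")) unname(corners(b)) else as.numeric(b)
}

#' 1 - DICE bounding-box loss
#'
#' The training loss: one minus the DICE overlap of the predicted and
#' ground-truth boxes, `1 - 2|I| / (|pred| + |gt| + eps)`.  Intersection
#' width/height and box extents are clamped at zero, so the value lies
#' in `[0, 1]` for any real-valued prediction and the loss is
#' differentiable almost everywhere.  Corners may be in any consistent
#' units (normalized or pixels).
#'
#' @param pred predicted box: numeric `(x1, y1, x2, y2)` (unconstrained)
#'   or a [BoundingBox-class].
#' @param gt ground-truth box, same forms.
#' @param eps small denominator guard.
#' @return Scalar loss in `[0, 1]`.
#' @examples
#' diceBoxLoss(c(0, 0, 2, 2), c(1, 1, 3, 3))  # 0.75
#' @export
diceBoxLoss <- function(pred, gt, eps = 1e-7) {
  diceBoxLossBatch(matrix(asCorners(pred), 1L), matrix(asCorners(gt), 1L),
                   eps = eps)$loss
}

# Vectorized loss + gradient over an n x 4 batch of raw predictions.
diceBoxLossBatch <- function(pred, gt, eps = 1e-7) {
  px1 <- pred[, 1L]; py1 <- pred[, 2L]; px2 <- pred[, 3L]; py2 <- pred[, 4L]
  gx1 <- gt[, 1L];  gy1 <- gt[, 2L];  gx2 <- gt[, 3L];  gy2 <- gt[, 4L]
  wP <- pmax(0, px2 - px1); hP <- pmax(0, py2 - py1)
  areaP <- wP * hP
  areaG <- pmax(0, gx2 - gx1) * pmax(0, gy2 - gy1)
  ix <- pmax(0, pmin(px2, gx2) - pmax(px1, gx1))
  iy <- pmax(0, pmin(py2, gy2) - pmax(py1, gy1))
  I <- ix * iy
  den <- areaP + areaG + eps
  loss <- 1 - 2 * I / den

  # subgradients of the clamped terms
  dIdx1 <- -iy * (ix > 0) * (px1 >= gx1)   # d I / d px1
  dIdx2 <-  iy * (ix > 0) * (px2 <= gx2)
  dIdy1 <- -ix * (iy > 0) * (py1 >= gy1)
  dIdy2 <-  ix * (iy > 0) * (py2 <= gy2)
  dAdx1 <- -hP * (wP > 0); dAdx2 <- hP * (wP > 0)
  dAdy1 <- -wP * (hP > 0); dAdy2 <- wP * (hP > 0)
  # loss = 1 - 2 I / den  =>  dloss = -2 (dI * den - I * dA) / den^2
  f <- function(dI, dA) -2 * (dI * den - I * dA) / den^2
  grad <- cbind(f(dIdx1, dAdx1), f(dIdy1, dAdy1),
                f(dIdx2, dAdx2), f(dIdy2, dAdy2))
  list(loss = loss, grad = grad)
}

#' Random shift augmentation
#'
#' Translates the stack by integer offsets drawn uniformly from
#' `[-shiftRange, shiftRange]` on both axes (zero-filling vacated
#' pixels) and shifts the box corners by the same normalized offsets,
#' clipping to `[0, 1]`.  Draws that would push the box entirely out of
#' the frame are rejected and redrawn.
#'
#' @param image an [ImageSequence-class] or `rows x cols x frames` array.
#' @param box the ground-truth [BoundingBox-class].
#' @param shiftRange maximum |shift| in pixels; must be below half the
#'   smaller image dimension.
#' @return List with `image` (same type as the input), `box` and
#'   `shift = c(dx, dy)` (columns, rows).
#' @export
randomShiftAugment <- function(image, box, shiftRange = 20L) {
  isSeq <- is(image, "ImageSequence")
  a <- if (isSeq) image@data else image
  d <- dim(a)
  if (shiftRange >= min(d[1L], d[2L]) / 2)
    stop("shiftRange must be smaller than half the image size")
  co <- asCorners(box)
  for (try in seq_len(200L)) {
    dx <- sample(-shiftRange:shiftRange, 1L)
    dy <- sample(-shiftRange:shiftRange, 1L)
    nx1 <- min(max(co[1L] + dx / d[2L], 0), 1)
    ny1 <- min(max(co[2L] + dy / d[1L], 0), 1)
    nx2 <- min(max(co[3L] + dx / d[2L], 0), 1)
    ny2 <- min(max(co[4L] + dy / d[1L], 0), 1)
    if (nx2 > nx1 && ny2 > ny1) {
      out <- translateStack(a, dy, dx)
      if (isSeq) out <- imageSequence(out, echoTimes = image@echoTimes)
      return(list(image = out, box = boundingBox(nx1, ny1, nx2, ny2),
                  shift = c(dx = dx, dy = dy)))
    }
  }
  stop("could not draw a shift keeping the box in frame")
}

# Integer translation with zero fill; dy moves content down, dx right.
translateStack <- function(a, dy, dx) {
  d <- dim(a)
  out <- array(0, d)
  srcR <- max(1, 1 - dy):min(d[1L], d[1L] - dy)
  srcC <- max(1, 1 - dx):min(d[2L], d[2L] - dx)
  if (length(srcR) > 0 && length(srcC) > 0)
    out[srcR + dy, srcC + dx, ] <- a[srcR, srcC, , drop = FALSE]
  out
}

#' Subject-grouped stratified k-fold split plan
#'
#' Builds a [FoldPlan-class] in which all slices of a subject share one
#' partition.  Subjects are shuffled once; the k test partitions are k
#' nearly equal disjoint chunks whose union covers every subject (the
#' k-fold property).  Per fold, the validation set takes
#' `ceiling(valFrac * remaining)` subjects of the non-test remainder and
#' the rest train.  With 530 subjects, `testFrac = 0.2`, `valFrac = 0.1`
#' and `k = 5` this reproduces 106 test / 43 validation / 381 training
#' subjects (318 / 129 / 1143 images at 3 slices each).
#'
#' @param subjectIds character vector of subject ids.
#' @param testFrac,valFrac test and validation fractions; `valFrac`
#'   applies to the post-test remainder.
#' @param k number of folds (test chunk size is `n / k`, which matches
#'   `round(testFrac * n)` when `testFrac = 1/k`).
#' @param seed shuffle seed.
#' @return A validated [FoldPlan-class].
#' @examples
#' plan <- makeSplits(sprintf("s%03d", 1:530), seed = 1)
#' lengths(plan@folds[[1]])
#' @export
makeSplits <- function(subjectIds, testFrac = 0.2, valFrac = 0.1, k = 5L,
                       seed = 1L) {
  ids <- as.character(subjectIds)
  n <- length(ids)
  if (anyDuplicated(ids)) stop("subject ids must be unique")
  if (testFrac + valFrac >= 1) stop("testFrac + valFrac must be below 1")
  if (n < 2L * k) stop("too few subjects for the requested folds")
  shuffled <- withSeed(seed, sample(ids))
  bounds <- floor(seq(0, n, length.out = k + 1))
  folds <- vector("list", k)
  for (f in seq_len(k)) {
    test <- shuffled[(bounds[f] + 1L):bounds[f + 1L]]
    remaining <- setdiff(shuffled, test)
    nVal <- ceiling(valFrac * length(remaining))
    if (nVal < 1L || nVal >= length(remaining))
      stop("validation fraction leaves an empty partition")
    validation <- remaining[seq_len(nVal)]
    train <- remaining[-seq_len(nVal)]
    folds[[f]] <- list(train = train, validation = validation, test = test)
  }
  new("FoldPlan", k = as.integer(k), subjects = ids, folds = folds)
}

#' Build a training configuration
#'
#' Defaults follow the reference protocol: batch size 32, up to 300
#' epochs, Adam with initial learning rate `1e-4` decayed exponentially
#' (rate 0.96 per 100,000 steps), and +/-20 px shift augmentation.
#'
#' @param batchSize mini-batch size.
#' @param maxEpochs epoch cap.
#' @param initialLr initial Adam step size.
#' @param decayRate,decaySteps exponential decay schedule parameters.
#' @param shiftRange augmentation range in pixels (0 disables).
#' @param seed training RNG seed (shuffling, dropout, augmentation).
#' @return A [TrainConfig-class].
#' @export
trainConfig <- function(batchSize = 32L, maxEpochs = 300L, initialLr = 1e-4,
                        decayRate = 0.96, decaySteps = 1e5,
                        shiftRange = 20L, seed = 1L) {
  new("TrainConfig", batchSize = as.integer(batchSize),
      maxEpochs = as.integer(maxEpochs), initialLr = initialLr,
      decayRate = decayRate, decaySteps = as.numeric(decaySteps),
      shiftRange = as.integer(shiftRange), seed = as.integer(seed))
}

#' Learning rate at a given optimizer step
#'
#' `lr(t) = initialLr * decayRate^(t / decaySteps)` (continuous decay).
#'
#' @param cfg a [TrainConfig-class].
#' @param step optimizer step (0-based).
#' @return Numeric learning rate.
#' @examples
#' scheduledLr(trainConfig(), 0)       # 1e-4
#' scheduledLr(trainConfig(), 100000)  # 9.6e-5
#' @export
scheduledLr <- function(cfg, step)
  cfg@initialLr * cfg@decayRate^(step / cfg@decaySteps)

#' Assemble a detection dataset from a simulated cohort
#'
#' Selects the detector's input frames (first, fifth and ninth echoes by
#' default) from every phantom and collects images, ground-truth boxes,
#' masks and the subject index into the flat structure the trainer and
#' evaluator consume.
#'
#' @param cohort result of [simulateCohort()].
#' @param frameIndices 1-based echo indices to keep.
#' @return List with `images` (list of arrays), `boxes` (list of
#'   [BoundingBox-class]), `masks` (list of [ContourMasks-class]) and
#'   `index` (data.frame).
#' @export
detectionDataset <- function(cohort, frameIndices = c(1L, 5L, 9L)) {
  images <- lapply(cohort$samples, function(s)
    selectFrames(s@sequence, frameIndices)@data)
  list(images = images,
       boxes = lapply(cohort$samples, gtBox),
       masks = lapply(cohort$samples, contourMasksOf),
       index = cohort$index)
}

adamInit <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

adamStep <- function(params, grads, state, lr,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

# Mean validation loss in evaluation mode, in chunks to bound memory.
validationLoss <- function(model, images, gtMat, chunk = 64L) {
  n <- length(images)
  tot <- 0
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(n, s + chunk - 1L)
    out <- predictBoxes(model, images[idx], raw = TRUE)
    tot <- tot + sum(diceBoxLossBatch(out, gtMat[idx, , drop = FALSE])$loss)
  }
  tot / n
}

#' Train the detector on one split
#'
#' Minimizes the mean 1-DICE box loss with Adam under the exponential
#' learning-rate schedule, shuffling each epoch, applying on-the-fly
#' shift augmentation to the training images, and retaining the
#' parameters of the epoch with the lowest validation loss (no early
#' stopping; training always runs to `maxEpochs`).  All randomness
#' derives from `cfg@seed`, so identical `(model, data, cfg)` reproduce
#' the loss trace exactly.
#'
#' @param model an initialized [ViTModel-class].
#' @param data a dataset from [detectionDataset()] (fields `images`,
#'   `boxes`, `index`).
#' @param trainIdx,valIdx integer indices into `data$images`.
#' @param cfg a [TrainConfig-class].
#' @param verbose print per-epoch losses.
#' @return List with `model` (best-validation [ViTModel-class]),
#'   `finalModel`, `history` (data.frame epoch/trainLoss/valLoss/lr) and
#'   `bestEpoch`.
#' @export
trainDetector <- function(model, data, trainIdx, valIdx, cfg,
                          verbose = FALSE) {
  validObject(cfg)
  params <- model@params
  state <- adamInit(params)
  gtMat <- do.call(rbind, lapply(data$boxes, asCorners))
  valImages <- data$images[valIdx]
  history <- data.frame(epoch = integer(), trainLoss = numeric(),
                        valLoss = numeric(), lr = numeric())
  bestVal <- Inf; bestParams <- params; bestEpoch <- 0L

  withSeed(cfg@seed, {
    for (epoch in seq_len(cfg@maxEpochs)) {
      ord <- sample(trainIdx)
      epochLoss <- 0
      for (s in seq(1L, length(ord), by = cfg@batchSize)) {
        idx <- ord[s:min(length(ord), s + cfg@batchSize - 1L)]
        gts <- gtMat[idx, , drop = FALSE]
        patchList <- vector("list", length(idx))
        for (q in seq_along(idx)) {
          img <- data$images[[idx[q]]]
          if (cfg@shiftRange > 0L) {
            aug <- randomShiftAugment(img, gts[q, ], cfg@shiftRange)
            img <- aug$image
            gts[q, ] <- asCorners(aug$box)
          }
          patchList[[q]] <- patchify(img, model@config@patchSize)
        }
        cur <- new("ViTModel", config = model@config, params = params)
        fwd <- vitForwardBatch(cur, patchList, train = TRUE)
        lo <- diceBoxLossBatch(fwd$out, gts)
        if (any(!is.finite(lo$loss)))
          stop(sprintf("non-finite loss at epoch %d; aborting", epoch))
        grads <- vitBackwardBatch(cur, fwd, lo$grad / length(idx))
        upd <- adamStep(params, grads, state, scheduledLr(cfg, state$t))
        params <- upd$params; state <- upd$state
        epochLoss <- epochLoss + sum(lo$loss)
      }
      trainLoss <- epochLoss / length(ord)
      valModel <- new("ViTModel", config = model@config, params = params)
      valLoss <- validationLoss(valModel, valImages,
                                gtMat[valIdx, , drop = FALSE])
      history[epoch, ] <- list(epoch, trainLoss, valLoss,
                               scheduledLr(cfg, state$t))
      if (valLoss < bestVal) {
        bestVal <- valLoss; bestParams <- params; bestEpoch <- epoch
      }
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                        trainLoss, valLoss))
    }
  })
  list(model = new("ViTModel", config = model@config, params = bestParams),
       finalModel = new("ViTModel", config = model@config, params = params),
       history = history, bestEpoch = bestEpoch)
}
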