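# End-to-end pipeline: simulate -> train -> predict -> evaluate.
# Each stage logs its configuration hash, seed, package version and
# paths, so two runs with equal logs produce equal outputs.

logRun <- function(stage, cfg, seed, paths) {
  f <- tempfile()
  saveRDS(cfg, f)
  h <- unname(tools::md5sum(f))
  unlink(f)
  message(sprintf("[%s] ViTLV %s | config %s | seed %s | %s", stage,
                  as.character(utils::packageVersion("ViTLV")), h, seed,
                  paste(names(paths), unlist(paths), sep = "=",
                        collapse = " ")))
}

#' Simulate a phantom cohort to disk
#'
#' Writes one NIfTI stack and two PNG masks per image, plus a single
#' ground-truth annotation CSV, in the layout the other pipeline stages
#' consume: `stacks/<image_id>.nii.gz`, `masks/<image_id>_epi.png`,
#' `masks/<image_id>_endo.png`, `annotations.csv` and `index.csv`.
#'
#' @param outDir output directory (created if needed).
#' @param nSubjects number of synthetic subjects.
#' @param sliceTypes slice labels simulated per subject.
#' @param imageRows image size (square), pixels.
#' @param nEchoes echoes per stack.
#' @param noiseSigma,coilGradient forwarded to [phantomSpec()].
#' @param seed cohort seed.
#' @return Invisibly, the index data.frame.
#' @export
runSimulate <- function(outDir, nSubjects = 10L,
                        sliceTypes = c("basal", "middle", "apical"),
                        imageRows = 64L, nEchoes = 10L, noiseSigma = 2,
                        coilGradient = 0.15, seed = 1L) {
  dir.create(file.path(outDir, "stacks"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outDir, "masks"), showWarnings = FALSE)
  logRun("simulate", list(nSubjects = nSubjects, imageRows = imageRows,
                          nEchoes = nEchoes, noiseSigma = noiseSigma,
                          coilGradient = coilGradient),
         seed, list(out = outDir))
  co <- simulateCohort(nSubjects, sliceTypes = sliceTypes,
                       imageRows = imageRows, nEchoes = nEchoes,
                       noiseSigma = noiseSigma, coilGradient = coilGradient,
                       seed = seed)
  ann <- co$index
  ann$x1 <- ann$y1 <- ann$x2 <- ann$y2 <- NA_real_
  for (i in seq_along(co$samples)) {
    s <- co$samples[[i]]
    id <- co$index$image_id[i]
    writeImageStack(s@sequence, file.path(outDir, "stacks",
                                          paste0(id, ".nii.gz")))
    writeMask(epicardial(s), file.path(outDir, "masks", paste0(id, "_epi.png")))
    writeMask(endocardial(s), file.path(outDir, "masks", paste0(id, "_endo.png")))
    ann[i, c("x1", "y1", "x2", "y2")] <- unname(corners(s@gtBox))
  }
  writeAnnotations(ann, file.path(outDir, "annotations.csv"))
  utils::write.csv(co$index, file.path(outDir, "index.csv"), row.names = FALSE)
  invisible(co$index)
}

loadDataDir <- function(dataDir, frameIndices) {
  ann <- readAnnotations(file.path(dataDir, "annotations.csv"))
  idx <- utils::read.csv(file.path(dataDir, "index.csv"),
                         stringsAsFactors = FALSE)
  images <- lapply(ann$image_id, function(id)
    selectFrames(readImageStack(file.path(dataDir, "stacks",
                                          paste0(id, ".nii.gz"))),
                 frameIndices)@data)
  list(images = images, boxes = annotationBoxes(ann), index = idx,
       annotations = ann)
}

#' Train the detector on a simulated/stored cohort
#'
#' Loads the stacks and annotations written by [runSimulate()], selects
#' the input echoes, builds a subject-grouped [FoldPlan-class] and
#' trains one detector per requested fold, retaining each fold's
#' best-validation checkpoint and finally the best fold overall
#' (lowest validation loss).  Emits per-fold checkpoints and histories,
#' the fold plan and the selected model under `outDir`.
#'
#' @param dataDir directory produced by [runSimulate()].
#' @param outDir output directory.
#' @param vitCfg a [ViTConfig-class]; frames must match
#'   `length(frameIndices)`.
#' @param trainCfg a [TrainConfig-class].
#' @param frameIndices 1-based echo indices fed to the detector.
#' @param k folds in the plan.
#' @param foldIndices which folds to actually train (default all).
#' @param seed split / weight-init seed.
#' @param verbose forwarded to [trainDetector()].
#' @return Invisibly, a list with `modelPath`, `foldPlan`, `bestFold`
#'   and `histories`.
#' @export
runTrain <- function(dataDir, outDir, vitCfg, trainCfg,
                     frameIndices = c(1L, 5L, 9L), k = 5L,
                     foldIndices = seq_len(k), seed = 1L, verbose = FALSE) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logRun("train", list(vit = configToList(vitCfg), k = k,
                       folds = foldIndices), seed,
         list(data = dataDir, out = outDir))
  data <- loadDataDir(dataDir, frameIndices)
  plan <- makeSplits(unique(data$index$subject_id), k = k, seed = seed)
  jsonlite::write_json(
    lapply(plan@folds, function(f) f),
    file.path(outDir, "fold_plan.json"))
  histories <- list(); bestVal <- Inf; bestFold <- NA_integer_
  for (f in foldIndices) {
    fold <- plan@folds[[f]]
    trainIdx <- which(data$index$subject_id %in% fold$train)
    valIdx <- which(data$index$subject_id %in% fold$validation)
    model <- vitModel(vitCfg, seed = seed + f)
    fit <- trainDetector(model, data, trainIdx, valIdx, trainCfg,
                         verbose = verbose)
    ck <- file.path(outDir, sprintf("fold%d.rds", f))
    saveModel(fit$model, ck)
    utils::write.csv(fit$history,
                     file.path(outDir, sprintf("fold%d_history.csv", f)),
                     row.names = FALSE)
    histories[[as.character(f)]] <- fit$history
    v <- min(fit$history$valLoss)
    if (v < bestVal) { bestVal <- v; bestFold <- f }
  }
  best <- file.path(outDir, "best_model.rds")
  file.copy(file.path(outDir, sprintf("fold%d.rds", bestFold)), best,
            overwrite = TRUE)
  file.copy(file.path(outDir, sprintf("fold%d.rds.json", bestFold)),
            paste0(best, ".json"), overwrite = TRUE)
  invisible(list(modelPath = best, foldPlan = plan, bestFold = bestFold,
                 histories = histories))
}

#' Predict boxes for every stack in a data directory
#'
#' Deterministic evaluation-mode inference with a saved checkpoint; one
#' predicted box per image, written in the annotation schema.
#'
#' @param modelPath checkpoint from [saveModel()]/[runTrain()].
#' @param dataDir directory with `stacks/` and `annotations.csv` (the
#'   latter only for image ids and slice labels).
#' @param outPath output annotation CSV/JSON path.
#' @param frameIndices echo indices fed to the detector.
#' @return Invisibly, the prediction data.frame.
#' @export
runPredict <- function(modelPath, dataDir, outPath,
                       frameIndices = c(1L, 5L, 9L)) {
  model <- loadModel(modelPath)
  logRun("predict", configToList(model@config), NA,
         list(model = modelPath, data = dataDir, out = outPath))
  data <- loadDataDir(dataDir, frameIndices)
  boxes <- predictBoxes(model, data$images)
  pred <- data$annotations
  for (i in seq_along(boxes))
    pred[i, c("x1", "y1", "x2", "y2")] <- unname(corners(boxes[[i]]))
  writeAnnotations(pred, outPath)
  invisible(pred)
}

#' Evaluate predicted against ground-truth annotations
#'
#' Joins predictions and ground truth on `image_id`, computes the
#' per-image metric records (using masks when a mask directory is
#' given) and writes `<outPrefix>_records.csv` plus the per-slice /
#' Global summary `<outPrefix>_summary.csv`.
#'
#' @param predPath,gtPath annotation files.
#' @param masksDir optional directory of `<image_id>_epi.png` /
#'   `<image_id>_endo.png` masks (enables the fractional errors and
#'   CIR).
#' @param outPrefix output path prefix.
#' @return Invisibly, a list with `records` and `summary`.
#' @export
runEvaluate <- function(predPath, gtPath, masksDir = NULL,
                        outPrefix = "evaluation") {
  pred <- readAnnotations(predPath)
  gt <- readAnnotations(gtPath)
  logRun("evaluate", list(), NA,
         list(pred = predPath, gt = gtPath, out = outPrefix))
  m <- match(gt$image_id, pred$image_id)
  if (anyNA(m)) stop("predictions missing for some ground-truth images")
  pred <- pred[m, ]
  masks <- NULL
  if (!is.null(masksDir))
    masks <- lapply(gt$image_id, function(id)
      contourMasks(readMask(file.path(masksDir, paste0(id, "_epi.png"))),
                   readMask(file.path(masksDir, paste0(id, "_endo.png")))))
  records <- evaluateDetections(
    as.matrix(pred[, c("x1", "y1", "x2", "y2")]),
    as.matrix(gt[, c("x1", "y1", "x2", "y2")]),
    sliceTypes = gt$slice_type, masks = masks, imageIds = gt$image_id)
  summary <- aggregateMetrics(records)
  utils::write.csv(records, paste0(outPrefix, "_records.csv"),
                   row.names = FALSE)
  utils::write.csv(summary, paste0(outPrefix, "_summary.csv"),
                   row.names = FALSE)
  invisible(list(records = records, summary = summary))
}
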