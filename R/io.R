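# File formats: NIfTI stacks (with a JSON sidecar for echo times), PNG
# or NIfTI masks, CSV/JSON box annotations, YAML run configurations and
# model checkpoints.

sidecarPath <- function(path) paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")

#' Read / write a multi-frame image stack
#'
#' Stacks are stored as 3-D NIfTI volumes (`.nii` / `.nii.gz`), axis
#' order rows x cols x frames.  NIfTI headers carry no echo-train
#' timing, so echo times travel in a small JSON sidecar
#' (`<stack>.json`) written and read automatically.
#'
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @return `readImageStack()`: an [ImageSequence-class].
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' x <- imageSequence(array(rnorm(8 * 8 * 3), c(8, 8, 3)),
#'                    echoTimes = c(2, 11.04, 20.08))
#' writeImageStack(x, f)
#' echoTimes(readImageStack(f))
#' @export
readImageStack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  vol <- RNifti::readNifti(path)
  a <- as.array(vol)
  a <- array(as.vector(a), dim(a))  # strip the niftiImage class
  if (length(dim(a)) == 2L)
    stop("expected a rows x cols x frames stack, got a 2-D image")
  if (length(dim(a)) != 3L)
    stop("expected a 3-D stack, got ", length(dim(a)), " dimensions")
  te <- rep(NA_real_, dim(a)[3L])
  sc <- sidecarPath(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!is.null(meta$echo_times) && length(meta$echo_times) == dim(a)[3L])
      te <- as.numeric(meta$echo_times)
  }
  storage.mode(a) <- "double"
  imageSequence(a, echoTimes = te)
}

#' @rdname readImageStack
#' @param x an [ImageSequence-class].
#' @param pixdim optional numeric pixel spacing `(row, col)` in mm,
#'   stored in the NIfTI header.
#' @export
writeImageStack <- function(x, path, pixdim = NULL) {
  stopifnot(is(x, "ImageSequence"))
  img <- RNifti::asNifti(x@data)
  if (!is.null(pixdim)) RNifti::pixdim(img)[1:2] <- pixdim
  RNifti::writeNifti(img, path)
  jsonlite::write_json(list(echo_times = x@echoTimes),
                       sidecarPath(path), auto_unbox = FALSE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read / write a binary mask
#'
#' PNG masks are stored 0/255 grayscale; NIfTI masks 0/1.  The format is
#' chosen by extension.
#'
#' @param path file path ending in `.png`, `.nii` or `.nii.gz`.
#' @return `readMask()`: logical matrix.
#' @export
readMask <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.png$", path)) {
    m <- png::readPNG(path)
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    m >= 0.5
  } else {
    a <- as.array(RNifti::readNifti(path))
    if (length(dim(a)) == 3L && dim(a)[3L] == 1L) a <- a[, , 1L]
    if (length(dim(a)) != 2L) stop("mask must be a single 2-D image")
    a != 0
  }
}

#' @rdname readMask
#' @param mask logical (or 0/1) matrix.
#' @export
writeMask <- function(mask, path) {
  m <- mask != 0
  if (grepl("\\.png$", path)) {
    png::writePNG(m * 1, path)
  } else {
    RNifti::writeNifti(RNifti::asNifti(array(m * 1, dim(m))), path)
  }
  invisible(path)
}

annotationCols <- c("image_id", "slice_type", "x1", "y1", "x2", "y2")

#' Read / write box annotations
#'
#' The exchange schema is one row per image: `image_id`, `slice_type`,
#' `x1`, `y1`, `x2`, `y2` (normalized top-left / bottom-right corners).
#' CSV and JSON are supported by extension.  Invalid rows are rejected
#' with their line numbers.
#'
#' @param path file path (`.csv` or `.json`).
#' @return `readAnnotations()`: data.frame in schema order with valid
#'   boxes.
#' @export
readAnnotations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- if (grepl("\\.json$", path)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  missing <- setdiff(annotationCols, names(df))
  if (length(missing))
    stop("annotation file lacks column(s): ", paste(missing, collapse = ", "))
  df <- df[annotationCols]
  for (col in c("x1", "y1", "x2", "y2")) df[[col]] <- as.numeric(df[[col]])
  bad <- which(!is.finite(df$x1) | !is.finite(df$y1) |
                 !is.finite(df$x2) | !is.finite(df$y2) |
                 df$x1 < 0 | df$y1 < 0 | df$x2 > 1 | df$y2 > 1 |
                 df$x1 >= df$x2 | df$y1 >= df$y2)
  if (length(bad))
    stop("invalid box on row(s) ", paste(bad, collapse = ", "),
         " of ", path, " (need 0 <= x1 < x2 <= 1 and 0 <= y1 < y2 <= 1)")
  df
}

#' @rdname readAnnotations
#' @param annotations data.frame in the annotation schema (extra columns
#'   are dropped).
#' @export
writeAnnotations <- function(annotations, path) {
  df <- annotations[annotationCols]
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(df, path, dataframe = "rows", digits = NA)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Boxes of an annotation data.frame as a list
#' @param annotations data.frame from [readAnnotations()].
#' @return List of [BoundingBox-class].
#' @export
annotationBoxes <- function(annotations)
  lapply(seq_len(nrow(annotations)), function(i)
    boundingBox(annotations$x1[i], annotations$y1[i],
                annotations$x2[i], annotations$y2[i]))

runConfigDefaults <- function() list(
  seed = 1L,
  phantom = list(n_subjects = 10L, image_rows = 64L, n_echoes = 10L,
                 noise_sigma = 2, coil_gradient = 0.15),
  frames = c(1L, 5L, 9L),
  vit = list(patch_size = 16L, embed_dim = 32L, n_heads = 4L,
             n_blocks = 2L, encoder_mlp_units = c(64L, 32L),
             head_mlp_units = c(512L, 128L, 32L),
             encoder_dropout = 0.1, head_dropout = 0.3,
             scale_convention = "paper", positional = "learned"),
  train = list(batch_size = 32L, max_epochs = 30L, initial_lr = 1e-3,
               decay_rate = 0.96, decay_steps = 1e5, shift_range = 5L),
  split = list(test_frac = 0.2, val_frac = 0.1, k = 5L))

mergeConfig <- function(defaults, user, path = "") {
  for (nm in names(user)) {
    if (!nm %in% names(defaults))
      stop("unknown configuration key: ", paste0(path, nm))
    if (is.list(defaults[[nm]]) && is.list(user[[nm]]))
      defaults[[nm]] <- mergeConfig(defaults[[nm]], user[[nm]],
                                    paste0(path, nm, "."))
    else defaults[[nm]] <- user[[nm]]
  }
  defaults
}

#' Read a YAML run configuration
#'
#' Merges the file over the package defaults; unknown keys are rejected.
#' `NULL` reads the defaults.
#'
#' @param path YAML file path or `NULL`.
#' @return Nested configuration list.
#' @export
readRunConfig <- function(path = NULL) {
  cfg <- runConfigDefaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such file: ", path)
    cfg <- mergeConfig(cfg, yaml::read_yaml(path))
  }
  cfg
}

vitConfigFromList <- function(v, rows, cols, frames)
  vitConfig(rows = rows, cols = cols, frames = frames,
            patchSize = v$patch_size, embedDim = v$embed_dim,
            nHeads = v$n_heads, nBlocks = v$n_blocks,
            encoderMlpUnits = v$encoder_mlp_units,
            headMlpUnits = v$head_mlp_units,
            encoderDropout = v$encoder_dropout,
            headDropout = v$head_dropout,
            scaleConvention = v$scale_convention,
            positional = v$positional)

configToList <- function(cfg) list(
  rows = cfg@rows, cols = cfg@cols, frames = cfg@frames,
  patch_size = cfg@patchSize, embed_dim = cfg@embedDim,
  n_heads = cfg@nHeads, n_blocks = cfg@nBlocks,
  encoder_mlp_units = cfg@encoderMlpUnits,
  head_mlp_units = cfg@headMlpUnits,
  encoder_dropout = cfg@encoderDropout, head_dropout = cfg@headDropout,
  scale_convention = cfg@scaleConvention, positional = cfg@positional)

#' Save / load a detector checkpoint
#'
#' Parameters are serialized with `saveRDS()`; the architecture
#' configuration travels in a JSON sidecar (`<file>.json`) so the
#' checkpoint is self-describing and the configuration round-trip is
#' lossless.
#'
#' @param model a [ViTModel-class].
#' @param path checkpoint path (conventionally `.rds`).
#' @return `loadModel()`: the reconstructed [ViTModel-class].
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "ViTModel"))
  saveRDS(model@params, path)
  jsonlite::write_json(configToList(model@config), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  scPath <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(scPath))
    stop("checkpoint or its .json sidecar missing at ", path)
  cl <- jsonlite::read_json(scPath, simplifyVector = TRUE)
  cfg <- vitConfig(rows = cl$rows, cols = cl$cols, frames = cl$frames,
                   patchSize = cl$patch_size, embedDim = cl$embed_dim,
                   nHeads = cl$n_heads, nBlocks = cl$n_blocks,
                   encoderMlpUnits = cl$encoder_mlp_units,
                   headMlpUnits = cl$head_mlp_units,
                   encoderDropout = cl$encoder_dropout,
                   headDropout = cl$head_dropout,
                   scaleConvention = cl$scale_convention,
                   positional = cl$positional)
  params <- readRDS(path)
  expect <- paramShapes(cfg)
  for (nm in names(expect)) {
    have <- if (is.matrix(params[[nm]])) dim(params[[nm]]) else length(params[[nm]])
    if (is.null(params[[nm]]) || !identical(as.integer(have),
                                            as.integer(expect[[nm]])))
      stop(sprintf("checkpoint/config mismatch for '%s': expected %s, found %s",
                   nm, paste(expect[[nm]], collapse = "x"),
                   paste(have %||% "nothing", collapse = "x")))
  }
  new("ViTModel", config = cfg, params = params)
}
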