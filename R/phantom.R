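# Synthetic short-axis multi-echo relaxometry phantoms.
#
# Every pixel belongs to one tissue and decays mono-exponentially,
# S(TE) = S0 * exp(-TE / T2*), shaded by a multiplicative coil-sensitivity
# gradient, with additive Gaussian noise on top.  The left ventricle is an
# annulus between two concentric rasterized ellipses (epicardial outside,
# endocardial inside) whose semi-axes shrink from basal to apical slices.

# Evaluate `expr` under a private RNG stream, restoring the caller's state.
withSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hadSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

defaultTissueRelaxation <- function() {
  # s0 in arbitrary units; t2 (decay constant) in ms.  Myocardium t2 = NA
  # means "draw per sample" from myoT2Range.  Blood/liver/chest wall/lung
  # values are plausible 1.5 T bright-blood defaults, not literature fits.
  list(myocardium = c(s0 = 100, t2 = NA_real_),
       blood      = c(s0 = 150, t2 = 80),
       liver      = c(s0 = 90,  t2 = 20),
       chest_wall = c(s0 = 80,  t2 = 25),
       lung       = c(s0 = 20,  t2 = 5),
       background = c(s0 = 3,   t2 = 50))
}

#' Build a phantom specification
#'
#' Returns a [PhantomSpec-class] describing one synthetic short-axis
#' multi-echo acquisition.  Defaults emulate a 256 x 256 bright-blood
#' T2* gradient-echo protocol: ten echoes starting at 2.0 ms with 2.26 ms
#' spacing, slice-dependent left-ventricle size (apical smallest), an
#' off-centre LV, 1--3 bright elliptical confounders, linear coil shading
#' and additive Gaussian noise.  Left-ventricle radius ranges and the
#' centre jitter scale linearly with the image size so reduced-resolution
#' phantoms keep the same anatomy.
#'
#' @param sliceType `"basal"`, `"middle"` or `"apical"`.
#' @param imageRows,imageCols image size in pixels.
#' @param nEchoes number of echo times.
#' @param te1,teSpacing echo-train timing, ms.
#' @param epiRadiusRange,endoRadiusRange semi-axis ranges in pixels;
#'   defaults depend on `sliceType` and scale with `imageRows / 256`.
#' @param centreJitter maximum LV-centre offset (pixels) from
#'   `centreAnchor`, drawn uniformly per axis.
#' @param centreAnchor `(row, col)` anchor for the LV centre, pixels.
#' @param tissueRelaxation named list `tissue -> c(s0, t2)`; see
#'   [PhantomSpec-class].
#' @param myoT2Range range (ms) for the per-sample myocardial decay
#'   constant; the default 2--57 ms spans the clinically observed global
#'   T2* spectrum from severe iron overload to normal.
#' @param noiseSigma additive Gaussian noise SD (arbitrary units).
#' @param coilGradient fractional intensity slope across the field.
#' @param confounderRange integer `c(min, max)` count of bright blobs.
#' @param seed default seed used by [generatePhantom()].
#' @return A validated [PhantomSpec-class].
#' @examples
#' spec <- phantomSpec("apical", imageRows = 64, noiseSigma = 0)
#' spec@epiRadiusRange
#' @export
phantomSpec <- function(sliceType = c("middle", "basal", "apical"),
                        imageRows = 256L, imageCols = imageRows,
                        nEchoes = 10L, te1 = 2.0, teSpacing = 2.26,
                        epiRadiusRange = NULL, endoRadiusRange = NULL,
                        centreJitter = 25 * imageRows / 256,
                        centreAnchor = c(imageRows / 2, imageCols / 2),
                        tissueRelaxation = defaultTissueRelaxation(),
                        myoT2Range = c(2, 57),
                        noiseSigma = 2, coilGradient = 0.15,
                        confounderRange = c(1L, 3L),
                        seed = 1L) {
  sliceType <- match.arg(sliceType)
  s <- imageRows / 256
  if (is.null(epiRadiusRange))
    epiRadiusRange <- s * switch(sliceType,
      basal = c(30, 44), middle = c(24, 38), apical = c(16, 28))
  if (is.null(endoRadiusRange))
    endoRadiusRange <- s * switch(sliceType,
      basal = c(17, 28), middle = c(14, 24), apical = c(9, 17))
  new("PhantomSpec",
      imageRows = as.integer(imageRows), imageCols = as.integer(imageCols),
      nEchoes = as.integer(nEchoes), te1 = te1, teSpacing = teSpacing,
      sliceType = sliceType,
      epiRadiusRange = as.numeric(epiRadiusRange),
      endoRadiusRange = as.numeric(endoRadiusRange),
      centreJitter = as.numeric(centreJitter),
      centreAnchor = as.numeric(centreAnchor),
      tissueRelaxation = tissueRelaxation,
      myoT2Range = as.numeric(myoT2Range),
      noiseSigma = noiseSigma, coilGradient = coilGradient,
      confounderRange = as.integer(confounderRange),
      seed = as.integer(seed))
}

# Logical membership matrix of a rotated ellipse on the pixel grid
# (0-based pixel-centre coordinates; rr/cc from a cached grid).
ellipseMask <- function(rows, cols, centreRC, a, b, theta) {
  rr <- matrix(seq_len(rows) - 1, rows, cols)
  cc <- matrix(seq_len(cols) - 1, rows, cols, byrow = TRUE)
  dy <- rr - centreRC[1L]
  dx <- cc - centreRC[2L]
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  u * u + v * v <= 1
}

#' Generate one synthetic phantom study
#'
#' Simulates the multi-echo stack, contour masks, ground-truth bounding
#' box and per-segment decay constants for one short-axis slice.  The
#' pixel signal of tissue `t` at echo `k` is
#' `s0_t * exp(-TE_k / T_t)`, multiplied by the coil shading and summed
#' with zero-mean Gaussian noise.  Identical `(spec, seed)` pairs
#' reproduce the sample bit-for-bit.
#'
#' @param spec a [PhantomSpec-class].
#' @param seed RNG seed; defaults to `spec@seed`.
#' @return A [PhantomSample-class].
#' @examples
#' p <- generatePhantom(phantomSpec("middle", imageRows = 64), seed = 7)
#' p
#' @export
generatePhantom <- function(spec, seed = spec@seed) {
  validObject(spec)
  withSeed(seed, {
    R <- spec@imageRows; C <- spec@imageCols
    tes <- echoTimes(spec@nEchoes, te1 = spec@te1, spacing = spec@teSpacing)

    # LV geometry: concentric rotated ellipses, eccentricity <= 0.5.
    centre <- spec@centreAnchor +
      stats::runif(2, -spec@centreJitter, spec@centreJitter)
    aEpi <- stats::runif(1, spec@epiRadiusRange[1L], spec@epiRadiusRange[2L])
    axisRatio <- stats::runif(1, sqrt(1 - 0.5^2), 1)  # b/a for ecc <= 0.5
    bEpi <- aEpi * axisRatio
    minWall <- max(2, 0.1 * aEpi)
    aEndo <- min(stats::runif(1, spec@endoRadiusRange[1L], spec@endoRadiusRange[2L]),
                 aEpi - minWall)
    bEndo <- max(aEndo * axisRatio, 1)
    theta <- stats::runif(1, 0, pi)
    if (centre[1L] - aEpi < 0 || centre[1L] + aEpi > R - 1 ||
        centre[2L] - aEpi < 0 || centre[2L] + aEpi > C - 1)
      stop("LV geometry does not fit in the image; reduce radii or jitter")

    epi <- ellipseMask(R, C, centre, aEpi, bEpi, theta)
    endo <- ellipseMask(R, C, centre, aEndo, bEndo, theta)
    endo <- endo & epi
    if (!any(endo) || !any(epi & !endo))
      stop("degenerate LV geometry: empty blood pool or myocardium")

    # Tissue map painted back-to-front: background, body (chest wall
    # shell), lungs, liver, then the LV and confounders on top.
    tiss <- matrix("background", R, C)
    body <- ellipseMask(R, C, c(R * 0.52, C * 0.5), 0.46 * C, 0.40 * R, 0)
    inner <- ellipseMask(R, C, c(R * 0.52, C * 0.5),
                         0.46 * C - 0.04 * C, 0.40 * R - 0.04 * R, 0)
    tiss[body & !inner] <- "chest_wall"
    lungL <- ellipseMask(R, C, c(R * 0.38, C * 0.23), 0.13 * C, 0.18 * R,
                         0.3) & inner
    lungR <- ellipseMask(R, C, c(R * 0.38, C * 0.77), 0.13 * C, 0.18 * R,
                         -0.3) & inner
    tiss[lungL | lungR] <- "lung"
    liver <- ellipseMask(R, C, c(R * 0.78, C * 0.30), 0.18 * C, 0.12 * R,
                         0.2) & inner
    tiss[liver] <- "liver"
    tiss[epi] <- "myocardium"
    tiss[endo] <- "blood"

    # Bright isointense confounders outside the LV.
    nConf <- sample(spec@confounderRange[1L]:spec@confounderRange[2L], 1L)
    for (i in seq_len(nConf)) {
      for (try in 1:25) {
        cc <- c(stats::runif(1, 0.12 * R, 0.88 * R),
                stats::runif(1, 0.12 * C, 0.88 * C))
        ra <- stats::runif(1, 0.02 * R, 0.06 * R)
        rb <- ra * stats::runif(1, 0.7, 1)
        blob <- ellipseMask(R, C, cc, ra, rb, stats::runif(1, 0, pi))
        if (!any(blob & epi)) { tiss[blob] <- "blood"; break }
      }
    }
    tiss[endo] <- "blood"; tiss[epi & !endo] <- "myocardium"

    # Per-pixel relaxation parameters.
    myoT2 <- spec@tissueRelaxation$myocardium[["t2"]]
    if (is.na(myoT2))
      myoT2 <- stats::runif(1, spec@myoT2Range[1L], spec@myoT2Range[2L])
    s0map <- matrix(0, R, C); t2map <- matrix(1, R, C)
    for (t in names(spec@tissueRelaxation)) {
      sel <- tiss == t
      pars <- spec@tissueRelaxation[[t]]
      s0map[sel] <- pars[["s0"]]
      t2map[sel] <- if (t == "myocardium") myoT2 else pars[["t2"]]
    }

    # Multiplicative linear coil-sensitivity shading.
    phi <- stats::runif(1, 0, 2 * pi)
    rr <- matrix((seq_len(R) - 0.5) / R - 0.5, R, C)
    cc2 <- matrix((seq_len(C) - 0.5) / C - 0.5, R, C, byrow = TRUE)
    gain <- 1 + spec@coilGradient * 2 * (cos(phi) * cc2 + sin(phi) * rr)

    stack <- array(0, c(R, C, spec@nEchoes))
    for (k in seq_along(tes)) {
      img <- s0map * exp(-tes[k] / t2map) * gain
      if (spec@noiseSigma > 0)
        img <- img + stats::rnorm(R * C, sd = spec@noiseSigma)
      stack[, , k] <- img
    }

    masks <- contourMasks(epi, endo)
    nSeg <- if (spec@sliceType == "apical") 4L else 6L
    new("PhantomSample",
        sequence = imageSequence(stack, echoTimes = tes),
        masks = masks,
        gtBox = bboxFromMask(epi),
        sliceType = spec@sliceType,
        segmentT2 = rep(myoT2, nSeg),
        myocardialT2 = myoT2)
  })
}

#' Subset the frames of a stack
#'
#' Frame indices are 1-based, matching the protocol wording "first,
#' fifth, and ninth echo times"; the echo-time metadata is subset along
#' with the frames.
#'
#' @param x an [ImageSequence-class].
#' @param frameIndices integer vector of 1-based frame indices.
#' @return An [ImageSequence-class] with `length(frameIndices)` frames in
#'   the requested order.
#' @examples
#' x <- imageSequence(array(rnorm(8 * 8 * 10), c(8, 8, 10)),
#'                    echoTimes = echoTimes(10, 2.0, 2.26))
#' echoTimes(selectFrames(x, c(1, 5, 9)))
#' @export
selectFrames <- function(x, frameIndices) {
  stopifnot(is(x, "ImageSequence"))
  nf <- dim(x@data)[3L]
  idx <- as.integer(frameIndices)
  if (length(idx) < 1L || anyNA(idx) || any(idx < 1L) || any(idx > nf))
    stop(sprintf("frame indices must lie in 1..%d", nf))
  imageSequence(x@data[, , idx, drop = FALSE], echoTimes = x@echoTimes[idx])
}

#' Simulate a cohort of subjects
#'
#' Generates `nSubjects` synthetic subjects, each contributing one slice
#' per entry of `sliceTypes` (basal/middle/apical by default, as in a
#' standard T2* protocol).  Within a subject the LV centre and the
#' myocardial decay constant are shared across slices, so
#' subject-grouped splitting is meaningful; slice geometry (radii,
#' eccentricity, rotation) varies per slice.
#'
#' @param nSubjects number of subjects.
#' @param sliceTypes character vector of slice labels per subject.
#' @param imageRows,imageCols image size, pixels.
#' @param nEchoes,noiseSigma,coilGradient forwarded to [phantomSpec()].
#' @param seed cohort seed; per-slice seeds are derived deterministically.
#' @return A list with `samples` (list of [PhantomSample-class]) and
#'   `index` (data.frame with `image_id`, `subject_id`, `slice_type`).
#' @examples
#' co <- simulateCohort(2, imageRows = 64, seed = 3)
#' co$index
#' @export
simulateCohort <- function(nSubjects,
                           sliceTypes = c("basal", "middle", "apical"),
                           imageRows = 256L, imageCols = imageRows,
                           nEchoes = 10L, noiseSigma = 2,
                           coilGradient = 0.15, seed = 1L) {
  samples <- vector("list", nSubjects * length(sliceTypes))
  ids <- subj <- sl <- character(length(samples))
  k <- 0L
  for (i in seq_len(nSubjects)) {
    subSeed <- (as.numeric(seed) * 10007 + i * 7919) %% 2147483647
    subjectDraw <- withSeed(subSeed, {
      list(centre = c(imageRows / 2, imageCols / 2) +
             stats::runif(2, -25 * imageRows / 256, 25 * imageRows / 256),
           myoT2 = stats::runif(1, 2, 57))
    })
    for (j in seq_along(sliceTypes)) {
      tr <- defaultTissueRelaxation()
      tr$myocardium[["t2"]] <- subjectDraw$myoT2
      spec <- phantomSpec(sliceTypes[j], imageRows = imageRows,
                          imageCols = imageCols, nEchoes = nEchoes,
                          centreJitter = 2 * imageRows / 256,
                          centreAnchor = subjectDraw$centre,
                          tissueRelaxation = tr,
                          noiseSigma = noiseSigma,
                          coilGradient = coilGradient)
      k <- k + 1L
      samples[[k]] <- generatePhantom(spec, seed = (subSeed + j * 131) %% 2147483647)
      subj[k] <- sprintf("subj%04d", i)
      sl[k] <- sliceTypes[j]
      ids[k] <- sprintf("subj%04d_%s", i, sliceTypes[j])
    }
  }
  list(samples = samples,
       index = data.frame(image_id = ids, subject_id = subj,
                          slice_type = sl, stringsAsFactors = FALSE))
}
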