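# Vision-Transformer bounding-box regressor.
#
# Pipeline: patchify -> linear patch embedding + positional encoding ->
# nBlocks transformer encoder blocks (pre-LN MHSA and MLP, both wrapped
# in skip connections) -> final layer norm -> flatten all tokens ->
# regression MLP -> 4 box coordinates (x1, y1, x2, y2, normalized).
#
# Everything is plain base R on BLAS; gradients are hand-derived in
# vit_grad.R and checked against finite differences in the test suite.

LN_EPS <- 1e-6

#' Build a ViT detector configuration
#'
#' Defaults are the reference detector for 256 x 256 three-frame stacks:
#' patch size 32 (64 patches), embedding width 64, 4 attention heads
#' (dropout 0.1), encoder MLP 128/64 (dropout 0.1), regression head
#' 2048/1024/512/64/32 (dropout 0.3), and 4 encoder blocks.  The encoder
#' depth is not part of the published hyper-parameter list; 4 blocks
#' matches the public Keras object-detection ViT this architecture
#' follows, and is configurable.
#'
#' @param rows,cols,frames input stack dimensions.
#' @param patchSize patch edge length (pixels).
#' @param embedDim token width D.
#' @param nHeads attention heads (D must be divisible by it).
#' @param nBlocks encoder depth.
#' @param encoderMlpUnits encoder MLP widths (last must equal D).
#' @param headMlpUnits regression-head widths (a linear 4-unit output
#'   layer is appended automatically).
#' @param encoderDropout,headDropout dropout rates.
#' @param scaleConvention `"paper"` (divide attention logits by
#'   `sqrt(dHead/nHeads)`) or `"per_head"` (`sqrt(dHead)`); see the
#'   vignette for why both exist.
#' @param positional `"learned"` or `"sinusoidal"` positional encoding.
#' @return A validated [ViTConfig-class].
#' @examples
#' vitConfig()
#' @export
vitConfig <- function(rows = 256L, cols = 256L, frames = 3L,
                      patchSize = 32L, embedDim = 64L, nHeads = 4L,
                      nBlocks = 4L,
                      encoderMlpUnits = c(128L, embedDim),
                      headMlpUnits = c(2048L, 1024L, 512L, 64L, 32L),
                      encoderDropout = 0.1, headDropout = 0.3,
                      scaleConvention = c("paper", "per_head"),
                      positional = c("learned", "sinusoidal")) {
  new("ViTConfig", rows = as.integer(rows), cols = as.integer(cols),
      frames = as.integer(frames), patchSize = as.integer(patchSize),
      embedDim = as.integer(embedDim), nHeads = as.integer(nHeads),
      nBlocks = as.integer(nBlocks),
      encoderMlpUnits = as.integer(encoderMlpUnits),
      headMlpUnits = as.integer(headMlpUnits),
      encoderDropout = encoderDropout, headDropout = headDropout,
      scaleConvention = match.arg(scaleConvention),
      positional = match.arg(positional))
}

#' Reduced configuration for desk-scale experiments
#'
#' A scaled-down detector for 64 x 64 three-frame stacks: patch size 16
#' (16 patches), embedding width 32, 4 heads, 2 encoder blocks, encoder
#' MLP 64/32 and regression head 512/128/32.  Used by the package's own
#' scaled-down training experiments and vignette.
#'
#' @return A [ViTConfig-class].
#' @export
reducedViTConfig <- function() {
  vitConfig(rows = 64L, cols = 64L, frames = 3L, patchSize = 16L,
            embedDim = 32L, nHeads = 4L, nBlocks = 2L,
            encoderMlpUnits = c(64L, 32L),
            headMlpUnits = c(512L, 128L, 32L))
}

nPatches <- function(config)
  (config@rows %/% config@patchSize) * (config@cols %/% config@patchSize)

patchDim <- function(config) config@patchSize^2 * config@frames

# Truncated-normal init (+-2 sd), standard ViT practice.
truncNorm <- function(n, sd = 0.02) {
  u <- stats::runif(n, stats::pnorm(-2), stats::pnorm(2))
  stats::qnorm(u) * sd
}

# Parameter names and dims as a pure function of the configuration.
paramShapes <- function(config) {
  D <- config@embedDim
  shapes <- list(embed_W = c(patchDim(config), D), embed_b = D)
  if (config@positional == "learned")
    shapes$pos <- c(nPatches(config), D)
  for (l in seq_len(config@nBlocks)) {
    p <- function(nm) paste0("blk", l, "_", nm)
    shapes[[p("ln1_g")]] <- D; shapes[[p("ln1_b")]] <- D
    for (nm in c("Wq", "Wk", "Wv", "Wo")) shapes[[p(nm)]] <- c(D, D)
    for (nm in c("bq", "bk", "bv", "bo")) shapes[[p(nm)]] <- D
    shapes[[p("ln2_g")]] <- D; shapes[[p("ln2_b")]] <- D
    inDim <- D
    for (j in seq_along(config@encoderMlpUnits)) {
      u <- config@encoderMlpUnits[j]
      shapes[[p(paste0("mlpW", j))]] <- c(inDim, u)
      shapes[[p(paste0("mlpb", j))]] <- u
      inDim <- u
    }
  }
  shapes$final_ln_g <- D; shapes$final_ln_b <- D
  inDim <- nPatches(config) * D
  dims <- c(config@headMlpUnits, 4L)
  for (j in seq_along(dims)) {
    shapes[[paste0("head_W", j)]] <- c(inDim, dims[j])
    shapes[[paste0("head_b", j)]] <- dims[j]
    inDim <- dims[j]
  }
  shapes
}

#' @rdname nParams
#' @export
setMethod("nParams", "ViTConfig", function(x)
  sum(vapply(paramShapes(x), prod, numeric(1))))

#' Initialize a ViT detector
#'
#' Weights are drawn from a truncated normal (sd 0.02), biases start at
#' zero and layer-norm gains at one.  The final regression bias is
#' initialized to the central box `(0.25, 0.25, 0.75, 0.75)` so that the
#' first predictions overlap plausible ground truth; the 1-DICE loss has
#' zero gradient on disjoint box pairs, so a zero-initialized head would
#' never start learning.
#'
#' @param config a [ViTConfig-class].
#' @param seed RNG seed for the weight draw.
#' @return A [ViTModel-class].
#' @examples
#' m <- vitModel(reducedViTConfig(), seed = 1)
#' nParams(m)
#' @export
vitModel <- function(config, seed = 1L) {
  validObject(config)
  shapes <- paramShapes(config)
  params <- withSeed(seed, lapply(names(shapes), function(nm) {
    d <- shapes[[nm]]
    if (grepl("ln", nm) && grepl("_g$", nm)) {
      rep(1, d)
    } else if (grepl("_b[qkvo]?$|_b$|ln.*_b$|mlpb|head_b", nm)) {
      rep(0, prod(d))
    } else if (length(d) == 2L) {
      matrix(truncNorm(prod(d)), d[1L], d[2L])
    } else {
      truncNorm(d)
    }
  }))
  names(params) <- names(shapes)
  lastB <- paste0("head_b", length(config@headMlpUnits) + 1L)
  params[[lastB]] <- c(0.25, 0.25, 0.75, 0.75)
  new("ViTModel", config = config, params = params)
}

# ---- patchify ---------------------------------------------------------

.patchIdxCache <- new.env(parent = emptyenv())

# Linear-index map into an (R, C, Nf) array: row k of the result indexes
# the row-major flattening of patch k (patches ordered row-major over the
# patch grid; within a patch, frame blocks are concatenated, each block
# flattened row by row).
patchIndexMap <- function(rows, cols, frames, P) {
  key <- paste(rows, cols, frames, P, sep = "x")
  if (!is.null(.patchIdxCache[[key]])) return(.patchIdxCache[[key]])
  gr <- rows %/% P; gc <- cols %/% P
  N <- gr * gc
  idx <- matrix(0L, N, P * P * frames)
  one <- integer(P * P)  # row-major in-patch offsets for frame 1
  k <- 0L
  for (i in seq_len(P)) for (j in seq_len(P)) {
    k <- k + 1L
    one[k] <- (j - 1L) * rows + i  # column-major linear index of (i, j)
  }
  frameOff <- (seq_len(frames) - 1L) * rows * cols
  patch <- as.integer(outer(one, frameOff, "+"))  # frame blocks concat
  n <- 0L
  for (pr in seq_len(gr)) for (pc in seq_len(gc)) {
    n <- n + 1L
    origin <- (pr - 1L) * P + (pc - 1L) * P * rows
    idx[n, ] <- patch + origin
  }
  .patchIdxCache[[key]] <- idx
  idx
}

#' Split a stack into flattened patches
#'
#' Divides the `rows x cols` plane into non-overlapping `P x P` patches
#' (rows and cols must be divisible by `P`; no padding) and flattens each
#' patch, across all frames, into one row of the result.  Patches are
#' ordered row-major over the patch grid and each row holds the
#' row-major flattening of its patch, one frame block after another, so
#' [unpatchify()] reproduces the stack exactly.
#'
#' @param x an [ImageSequence-class] or a `rows x cols x frames` array.
#' @param patchSize patch edge length P.
#' @return Numeric matrix with `rows * cols / P^2` rows and
#'   `P^2 * frames` columns.
#' @examples
#' x <- array(rnorm(64 * 64 * 3), c(64, 64, 3))
#' dim(patchify(x, 32))  # 4 x 3072
#' @export
patchify <- function(x, patchSize) {
  a <- if (is(x, "ImageSequence")) x@data else x
  if (length(dim(a)) != 3L) stop("input must be rows x cols x frames")
  d <- dim(a)
  if (d[1L] %% patchSize != 0L || d[2L] %% patchSize != 0L)
    stop("rows and cols must be divisible by the patch size (no padding)")
  idx <- patchIndexMap(d[1L], d[2L], d[3L], patchSize)
  m <- a[idx]
  dim(m) <- dim(idx)
  m
}

#' @rdname patchify
#' @param patches matrix produced by [patchify()].
#' @param rows,cols,frames original stack dimensions.
#' @return `unpatchify()`: the reassembled `rows x cols x frames` array.
#' @export
unpatchify <- function(patches, rows, cols, frames, patchSize) {
  idx <- patchIndexMap(rows, cols, frames, patchSize)
  stopifnot(identical(dim(idx), dim(patches)))
  a <- array(0, c(rows, cols, frames))
  a[as.integer(idx)] <- as.numeric(patches)
  a
}

# ---- embedding and attention primitives -------------------------------

addBias <- function(M, b) M + rep(b, each = nrow(M))

#' Sinusoidal positional-encoding table
#'
#' Classic fixed transformer encoding: `sin(k / 10000^(2i/D))` and
#' `cos(...)` interleaved across the embedding dimension.
#'
#' @param n number of positions (patches).
#' @param d embedding width.
#' @return `n x d` numeric matrix.
#' @export
sinusoidalPositions <- function(n, d) {
  pos <- matrix(0, n, d)
  k <- seq_len(n) - 1
  for (i in seq_len(ceiling(d / 2))) {
    w <- 1 / 10000^((2 * (i - 1)) / d)
    pos[, 2 * i - 1] <- sin(k * w)
    if (2 * i <= d) pos[, 2 * i] <- cos(k * w)
  }
  pos
}

#' Embed flattened patches into token space
#'
#' `X = patches %*% projection + positions` (plus an optional bias): the
#' learned linear embedding of each flattened patch with its positional
#' encoding added.
#'
#' @param patches `N x (P^2 * frames)` patch matrix.
#' @param projection `(P^2 * frames) x D` projection matrix.
#' @param positions `N x D` positional table.
#' @param bias optional length-D bias of the projection.
#' @return `N x D` token matrix.
#' @export
embedPatches <- function(patches, projection, positions,
                         bias = rep(0, ncol(projection))) {
  if (ncol(patches) != nrow(projection))
    stop("patch width does not match the projection input dimension")
  if (!identical(c(nrow(patches), ncol(projection)), dim(positions)[1:2]) &&
      !(nrow(positions) == nrow(patches) && ncol(positions) == ncol(projection)))
    stop("positional table must be N x D")
  addBias(patches %*% projection, bias) + positions
}

rowSoftmax <- function(S) {
  E <- exp(S - apply(S, 1L, max))
  E / rowSums(E)
}

#' Single-head self-attention
#'
#' Projects tokens into queries, keys and values (`Q = X W_Q`,
#' `K = X W_K`, `V = X W_V`), forms the attention matrix
#' `A = softmax(Q K^T / sqrt(D_q))` row-wise, and returns `Z = A V`.
#' Every row of `A` is a probability vector.
#'
#' @param X `N x D` token matrix.
#' @param Wq,Wk,Wv projection matrices; `ncol(Wq)` must equal `ncol(Wk)`.
#' @return List with `A` (`N x N` attention matrix) and `Z`
#'   (`N x ncol(Wv)` output).
#' @examples
#' X <- matrix(rnorm(8), 2, 4)
#' rowSums(selfAttention(X, diag(4), diag(4), diag(4))$A)
#' @export
selfAttention <- function(X, Wq, Wk, Wv) {
  if (!all(is.finite(X))) stop("non-finite token matrix")
  if (ncol(Wq) != ncol(Wk)) stop("query and key dimensions must agree (Dq = Dk)")
  Q <- X %*% Wq; K <- X %*% Wk; V <- X %*% Wv
  A <- rowSoftmax(Q %*% t(K) / sqrt(ncol(Wq)))
  list(A = A, Z = A %*% V)
}

#' Multi-head self-attention
#'
#' Runs `nHeads` self-attention heads on column slices of shared
#' `D x D` projections, concatenates the head outputs channel-wise and
#' applies the output projection `W_O`.  Under the `"paper"` scale
#' convention attention logits are divided by `sqrt(dHead / nHeads)`
#' (as the per-head expression is printed); `"per_head"` uses the
#' conventional `sqrt(dHead)`, with `dHead = D / nHeads`.
#'
#' @param X `N x D` token matrix.
#' @param attn named list with `Wq`, `Wk`, `Wv`, `Wo` (`D x D`) and
#'   optional biases `bq`, `bk`, `bv`, `bo`.
#' @param nHeads number of heads (D divisible by it).
#' @param scaleConvention `"paper"` or `"per_head"`.
#' @return `N x D` output token matrix.
#' @export
mhsa <- function(X, attn, nHeads, scaleConvention = c("paper", "per_head")) {
  scaleConvention <- match.arg(scaleConvention)
  D <- ncol(X)
  if (D %% nHeads != 0L) stop("embedDim must be divisible by nHeads")
  dHead <- D %/% nHeads
  scl <- if (scaleConvention == "paper") sqrt(dHead / nHeads) else sqrt(dHead)
  zero <- rep(0, D)
  Q <- addBias(X %*% attn$Wq, attn$bq %||% zero)
  K <- addBias(X %*% attn$Wk, attn$bk %||% zero)
  V <- addBias(X %*% attn$Wv, attn$bv %||% zero)
  Z <- matrix(0, nrow(X), D)
  for (i in seq_len(nHeads)) {
    ci <- ((i - 1L) * dHead + 1L):(i * dHead)
    A <- rowSoftmax(Q[, ci, drop = FALSE] %*% t(K[, ci, drop = FALSE]) / scl)
    Z[, ci] <- A %*% V[, ci, drop = FALSE]
  }
  addBias(Z %*% attn$Wo, attn$bo %||% zero)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

layerNorm <- function(X, g, b, eps = LN_EPS) {
  mu <- rowMeans(X)
  xc <- X - mu
  invstd <- 1 / sqrt(rowMeans(xc^2) + eps)
  addBias(xc * invstd * rep(g, each = nrow(X)), b)
}

gelu <- function(x) x * stats::pnorm(x)

#' Transformer encoder block (evaluation mode)
#'
#' Pre-norm block: `U = X + MHSA(LN(X))`, then
#' `X' = U + MLP(LN(U))`, where the MLP applies GELU-activated dense
#' layers of the configured widths.  Dropout is active only inside the
#' training loop, not in this evaluation-mode entry point.
#'
#' @param X `N x D` token matrix.
#' @param blockParams named list with `ln1_g`, `ln1_b`, `Wq`, `bq`, `Wk`,
#'   `bk`, `Wv`, `bv`, `Wo`, `bo`, `ln2_g`, `ln2_b` and `mlpW1`/`mlpb1`,
#'   `mlpW2`/`mlpb2`, ... (last MLP width = D).
#' @param nHeads attention heads.
#' @param scaleConvention see [mhsa()].
#' @return `N x D` token matrix.
#' @export
encoderBlock <- function(X, blockParams, nHeads,
                         scaleConvention = c("paper", "per_head")) {
  scaleConvention <- match.arg(scaleConvention)
  p <- blockParams
  U <- X + mhsa(layerNorm(X, p$ln1_g, p$ln1_b), p, nHeads, scaleConvention)
  H <- layerNorm(U, p$ln2_g, p$ln2_b)
  j <- 1L
  while (!is.null(p[[paste0("mlpW", j)]])) {
    H <- gelu(addBias(H %*% p[[paste0("mlpW", j)]], p[[paste0("mlpb", j)]]))
    j <- j + 1L
  }
  U + H
}

blockParamList <- function(params, l) {
  pre <- paste0("blk", l, "_")
  nm <- names(params)[startsWith(names(params), pre)]
  out <- params[nm]
  names(out) <- sub(pre, "", nm)
  out
}

positionsOf <- function(model) {
  cfg <- model@config
  if (cfg@positional == "learned") model@params$pos
  else sinusoidalPositions(nPatches(cfg), cfg@embedDim)
}

#' Run the detector on one stack
#'
#' Full forward pass in evaluation mode (dropout off, deterministic).
#' The four raw head outputs are interpreted as `(x1, y1, x2, y2)`
#' normalized corners; they are clipped to `[0, 1]` and corner-sorted so
#' the returned box is always valid.
#'
#' @param model a [ViTModel-class].
#' @param x an [ImageSequence-class] or array matching the model
#'   configuration.
#' @param raw if `TRUE`, return the unclipped 4-vector instead of a
#'   [BoundingBox-class].
#' @return A [BoundingBox-class] (or raw numeric 4-vector).
#' @examples
#' m <- vitModel(reducedViTConfig(), seed = 1)
#' predictBox(m, array(rnorm(64 * 64 * 3), c(64, 64, 3)))
#' @export
predictBox <- function(model, x, raw = FALSE) {
  out <- predictBoxes(model, list(x), raw = TRUE)[1L, ]
  if (raw) return(out)
  rawToBox(out)
}

# Clip to [0,1] and corner-sort a raw (x1,y1,x2,y2) output; degenerate
# (zero-extent) axes are widened by one part in 10^6 to keep the box valid.
rawToBox <- function(v) {
  v <- pmin(pmax(v, 0), 1)
  x <- sort(v[c(1L, 3L)]); y <- sort(v[c(2L, 4L)])
  eps <- 1e-6
  if (x[2L] - x[1L] < eps) { x[1L] <- max(0, x[1L] - eps); x[2L] <- min(1, x[2L] + eps) }
  if (y[2L] - y[1L] < eps) { y[1L] <- max(0, y[1L] - eps); y[2L] <- min(1, y[2L] + eps) }
  boundingBox(x[1L], y[1L], x[2L], y[2L])
}

#' @rdname predictBox
#' @param xs list of stacks (or of [ImageSequence-class]).
#' @return `predictBoxes()`: with `raw = TRUE` an `n x 4` matrix of raw
#'   outputs, otherwise a list of [BoundingBox-class].
#' @export
predictBoxes <- function(model, xs, raw = FALSE) {
  cfg <- model@config
  patches <- lapply(xs, function(x) {
    a <- if (is(x, "ImageSequence")) x@data else x
    d <- dim(a)
    if (!identical(as.integer(d), c(cfg@rows, cfg@cols, cfg@frames)))
      stop(sprintf("input is %s but the model expects %dx%dx%d",
                   paste(d, collapse = "x"), cfg@rows, cfg@cols, cfg@frames))
    patchify(a, cfg@patchSize)
  })
  out <- vitForwardBatch(model, patches, train = FALSE)$out
  if (raw) return(out)
  lapply(seq_len(nrow(out)), function(i) rawToBox(out[i, ]))
}
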