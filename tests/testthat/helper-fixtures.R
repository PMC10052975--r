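# Shared fixtures, built in code at test time.

# Filled disc mask on an n x n grid (0-based pixel-centre coordinates).
discMask <- function(n, centre, radius) {
  rr <- matrix(seq_len(n) - 1, n, n)
  cc <- matrix(seq_len(n) - 1, n, n, byrow = TRUE)
  (rr - centre[1])^2 + (cc - centre[2])^2 <= radius^2
}

# Tiny dropout-free ViT configuration for exactness checks.
tinyViTConfig <- function(encoderDropout = 0, headDropout = 0)
  vitConfig(rows = 16L, cols = 16L, frames = 2L, patchSize = 8L,
            embedDim = 8L, nHeads = 2L, nBlocks = 2L,
            encoderMlpUnits = c(12L, 8L), headMlpUnits = c(10L, 6L),
            encoderDropout = encoderDropout, headDropout = headDropout)

# Dropout-free reduced config (64 x 64 x 3) for deterministic training.
reducedNoDropConfig <- function()
  vitConfig(rows = 64L, cols = 64L, frames = 3L, patchSize = 16L,
            embedDim = 32L, nHeads = 4L, nBlocks = 2L,
            encoderMlpUnits = c(64L, 32L), headMlpUnits = c(512L, 128L, 32L),
            encoderDropout = 0, headDropout = 0)

# Random valid normalized boxes with a minimum edge length.
randomBoxes <- function(n, minEdge = 0) {
  t(vapply(seq_len(n), function(i) {
    repeat {
      x <- sort(runif(2)); y <- sort(runif(2))
      if (x[2] - x[1] >= minEdge && y[2] - y[1] >= minEdge)
        return(c(x[1], y[1], x[2], y[2]))
    }
  }, numeric(4)))
}

# Rasterized-area overlap oracle, independent of the closed-form path.
# Axis-aligned boxes factorize over the axes, so areas are counted on a
# fine 1-D midpoint raster per axis (g^2 sample points in effect).
rasterOverlap <- function(a, b, g = 10000L) {
  pts <- (seq_len(g) - 0.5) / g
  cnt <- function(lo, hi) sum(pts >= lo & pts < hi) / g
  areaA <- cnt(a[1], a[3]) * cnt(a[2], a[4])
  areaB <- cnt(b[1], b[3]) * cnt(b[2], b[4])
  I <- cnt(max(a[1], b[1]), min(a[3], b[3])) *
    cnt(max(a[2], b[2]), min(a[4], b[4]))
  list(iou = if (areaA + areaB - I <= 0) 0 else I / (areaA + areaB - I),
       dice = if (areaA + areaB <= 0) 0 else 2 * I / (areaA + areaB))
}
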