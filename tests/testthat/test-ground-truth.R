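test_that("bboxFromMask returns the tight half-open-extent box", {
  full <- matrix(TRUE, 100, 100)
  expect_equal(unname(corners(bboxFromMask(full))), c(0, 0, 1, 1))
  one <- matrix(FALSE, 100, 100); one[1, 1] <- TRUE
  expect_equal(unname(corners(bboxFromMask(one))), c(0, 0, 0.01, 0.01))
  rect <- matrix(FALSE, 100, 100); rect[11:20, 21:40] <- TRUE
  expect_equal(unname(corners(bboxFromMask(rect))), c(0.20, 0.10, 0.40, 0.20))
  expect_error(bboxFromMask(matrix(FALSE, 10, 10)), "empty mask")
})

test_that("bboxFromMask is monotone and stable under cropping to itself", {
  set.seed(1)
  for (i in 1:20) {
    m <- matrix(runif(400) < 0.2, 20, 20)
    if (!any(m)) next
    box <- bboxFromMask(m)
    # cropping the mask to its own box leaves the box unchanged
    co <- corners(box)
    r <- (floor(co["y1"] * 20) + 1):(ceiling(co["y2"] * 20))
    cc <- (floor(co["x1"] * 20) + 1):(ceiling(co["x2"] * 20))
    m2 <- matrix(FALSE, 20, 20); m2[r, cc] <- m[r, cc]
    expect_equal(corners(bboxFromMask(m2)), co)
    # monotone: a submask's box is contained in the full mask's box
    sub <- m & (matrix(runif(400), 20, 20) < 0.5)
    if (any(sub)) {
      cs <- corners(bboxFromMask(sub))
      expect_true(cs["x1"] >= co["x1"] && cs["y1"] >= co["y1"] &&
                    cs["x2"] <= co["x2"] && cs["y2"] <= co["y2"])
    }
  }
})

test_that("blood-pool centre is the tight-box midpoint and translates exactly", {
  disc <- discMask(100, c(50, 50), 10)
  expect_equal(unname(bpCentre(disc)), c(50, 50), tolerance = 0.5)
  rect <- matrix(FALSE, 100, 100); rect[11:20, 21:40] <- TRUE
  expect_equal(unname(bpCentre(rect)), c(15.0, 30.0))
  shifted <- matrix(FALSE, 100, 100); shifted[16:25, 28:47] <- TRUE
  expect_equal(unname(bpCentre(shifted)), c(15.0, 30.0) + c(5, 7))
  expect_error(bpCentre(matrix(FALSE, 5, 5)), "empty")
  # centroid variant agrees on symmetric shapes
  expect_equal(unname(bpCentre(rect, centre = "centroid")), c(15.0, 30.0))
})

test_that("equiangular segments partition the myocardium", {
  epi <- discMask(101, c(50, 50), 30)
  endo <- discMask(101, c(50, 50), 15)
  masks <- contourMasks(epi, endo)
  myo <- epi & !endo
  lab1 <- equiangularSegments(masks, 1)
  expect_true(all(lab1[myo] == 1L) && all(lab1[!myo] == 0L))
  for (n in c(4L, 6L)) {
    lab <- equiangularSegments(masks, n)
    expect_identical(lab != 0L, myo)          # exact support
    expect_setequal(unique(lab[myo]), seq_len(n))
    counts <- tabulate(lab[myo], n)
    # circular symmetry: per-sector counts equal within 5%
    expect_lt(max(abs(counts - mean(counts))) / mean(counts), 0.05)
  }
  expect_error(equiangularSegments(contourMasks(endo, endo), 4), "empty")
})

test_that("rotating the reference angle rotates the labels", {
  epi <- discMask(101, c(50, 50), 30)
  endo <- discMask(101, c(50, 50), 15)
  masks <- contourMasks(epi, endo)
  lab0 <- equiangularSegments(masks, 4, referenceAngle = 0)
  lab90 <- equiangularSegments(masks, 4, referenceAngle = pi / 2)
  myo <- epi & !endo
  # a quarter-turn reference shift relabels k -> k-1 (mod 4)
  expect_gt(mean((lab90[myo] %% 4L) + 1L == lab0[myo]), 0.95)
})

test_that("T2* fit is exact on noiseless decay and matches the two-point form", {
  tes <- echoTimes(10, 2.0, 2.26)
  f <- fitT2Star(100 * exp(-tes / 20), tes)
  expect_true(f$converged)
  expect_equal(f$t2star, 20, tolerance = 1e-6)
  expect_equal(f$s0, 100, tolerance = 1e-6)
  # closed-form two-point oracle: t2 = (te2 - te1) / log(s1 / s2)
  s <- c(83.2, 41.7); te <- c(3.1, 14.9)
  f2 <- fitT2Star(s, te)
  expect_equal(f2$t2star, (te[2] - te[1]) / log(s[1] / s[2]),
               tolerance = 1e-6)
  # degenerate constant signal: flagged, not an error
  f3 <- fitT2Star(rep(50, 10), tes)
  expect_false(f3$converged)
  expect_gt(f3$t2star, 1e6)
  expect_error(fitT2Star(c(-1, 2), c(1, 2)), "positive")
  expect_error(fitT2Star(5, 1), "pairs")
})

test_that("T2* estimation stays accurate at moderate noise", {
  tes <- echoTimes(10, 2.0, 2.26)
  clean <- 100 * exp(-tes / 20)
  set.seed(30)
  relErr <- replicate(500, {
    noisy <- pmax(clean + rnorm(10, sd = 100 / 30), 1e-3)
    abs(fitT2Star(noisy, tes)$t2star - 20) / 20
  })
  expect_lt(median(relErr), 0.05)
})

test_that("global T2* is the mean of exactly 16 segmental values", {
  expect_equal(globalT2Star(rep(30, 16)), 30)
  set.seed(2); v <- runif(16, 10, 50)
  expect_equal(globalT2Star(v), mean(v))
  expect_error(globalT2Star(rep(30, 15)), "16")
  expect_error(globalT2Star(rep(30, 17)), "16")
})

test_that("global T2* from a 6+6+4 phantom study recovers the generator value", {
  tr <- ViTLV:::defaultTissueRelaxation()
  tr$myocardium[["t2"]] <- 25
  segs <- integer(0); vals <- numeric(0)
  for (sl in c("basal", "middle", "apical")) {
    spec <- phantomSpec(sl, imageRows = 64, noiseSigma = 0,
                        coilGradient = 0, tissueRelaxation = tr)
    p <- generatePhantom(spec, seed = 17)
    n <- if (sl == "apical") 4L else 6L
    sa <- segmentalT2Star(imageSequenceOf(p), contourMasksOf(p), n)
    segs <- c(segs, n); vals <- c(vals, sa$segmentT2)
  }
  expect_equal(segs, c(6L, 6L, 4L))
  expect_equal(globalT2Star(vals), 25, tolerance = 1e-6)
})
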