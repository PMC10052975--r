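test_that("IoU and DICE agree with exact arithmetic on known boxes", {
  a <- c(0, 0, 2, 2); b <- c(1, 1, 3, 3)
  expect_equal(boxIoU(a, a), 1)
  expect_equal(boxDice(a, a), 1)
  expect_equal(boxIoU(a, c(3, 3, 4, 4)), 0)
  expect_equal(boxDice(a, c(3, 3, 4, 4)), 0)
  expect_equal(boxIoU(a, b), 1 / 7)    # I = 1, U = 4 + 4 - 1
  expect_equal(boxDice(a, b), 0.25)    # 2 * 1 / (4 + 4)
  bb <- boundingBox(0.25, 0.25, 0.75, 0.75)
  expect_equal(boxIoU(bb, bb), 1)
})

test_that("closed-form overlap matches the rasterized-area oracle", {
  set.seed(31)
  A <- randomBoxes(1000); B <- randomBoxes(1000)
  for (i in seq_len(1000)) {
    mc <- rasterOverlap(A[i, ], B[i, ])
    expect_lt(abs(boxIoU(A[i, ], B[i, ]) - mc$iou), 1e-2)
    expect_lt(abs(boxDice(A[i, ], B[i, ]) - mc$dice), 1e-2)
  }
})

test_that("DICE = 2 IoU / (1 + IoU) holds to machine precision", {
  set.seed(32)
  A <- randomBoxes(1000); B <- randomBoxes(1000)
  for (i in seq_len(1000)) {
    J <- boxIoU(A[i, ], B[i, ])
    expect_equal(boxDice(A[i, ], B[i, ]), 2 * J / (1 + J),
                 tolerance = 1e-12)
  }
})

test_that("centre-point errors follow the equal-area-circle normalization", {
  gt <- c(0.3, 0.3, 0.7, 0.7)
  masks <- contourMasks(discMask(100, c(50, 50), 10),
                        discMask(100, c(50, 50), 6))
  expect_equal(unname(centreErrors(gt, gt, masks)), c(0, 0, 0))
  # centre offset of 5 px against a radius-10 epicardial disc
  pred <- gt + c(0.05, 0, 0.05, 0)
  ce <- centreErrors(pred, gt, masks)
  expect_equal(ce[["epsCpA"]], 5, tolerance = 1e-9)
  expect_equal(ce[["epsCpEpi"]], 0.5, tolerance = 0.03)
  # doubling both mask areas divides the fractional errors by sqrt(2)
  rectEpi <- matrix(FALSE, 100, 100); rectEpi[31:50, 31:50] <- TRUE
  rectEndo <- matrix(FALSE, 100, 100); rectEndo[36:45, 36:45] <- TRUE
  rectEpi2 <- matrix(FALSE, 100, 100); rectEpi2[31:50, 21:60] <- TRUE
  rectEndo2 <- matrix(FALSE, 100, 100); rectEndo2[36:45, 31:50] <- TRUE
  ce1 <- centreErrors(pred, gt, contourMasks(rectEpi, rectEndo))
  ce2 <- centreErrors(pred, gt, contourMasks(rectEpi2, rectEndo2))
  expect_equal(ce2[["epsCpEpi"]], ce1[["epsCpEpi"]] / sqrt(2),
               tolerance = 1e-12)
  expect_equal(ce2[["epsCpEndo"]], ce1[["epsCpEndo"]] / sqrt(2),
               tolerance = 1e-12)
  expect_error(centreErrors(pred, gt, contourMasks(rectEpi * FALSE,
                                                   rectEndo * FALSE)))
})

test_that("CIR uses floor-to-pixel membership including boundary pixels", {
  endo <- discMask(100, c(50, 50), 8)
  expect_true(cirHit(c(0.4, 0.4, 0.6, 0.6), endo))      # centred on pool
  expect_false(cirHit(c(0.0, 0.0, 0.1, 0.1), endo))     # far corner
  expect_false(cirHit(c(0.9, 0.9, 1.1, 1.1), endo))     # centre off-image
  # 5 x 5 hand mask: centre pixel coordinates land exactly on a boundary
  # pixel of the mask; the containing pixel's membership decides
  m5 <- matrix(FALSE, 5, 5); m5[2:4, 2:4] <- TRUE
  # centre (0.3, 0.3) -> pixel floor(1.5) = 1 (0-based) -> row 2, col 2: hit
  expect_true(cirHit(c(0.1, 0.1, 0.5, 0.5), m5))
  # centre (0.9, 0.9) -> pixel 4 (0-based) -> row 5, col 5: miss
  expect_false(cirHit(c(0.8, 0.8, 1.0, 1.0), m5))
  # centre exactly on the first masked pixel's left edge: floor keeps it
  expect_true(cirHit(c(0.2, 0.2, 0.4, 0.4), m5))        # centre (0.3, 0.3)
  expect_error(cirHit(c(0.4, 0.4, 0.6, 0.6), m5 & FALSE), "empty")
})

test_that("per-image records satisfy the DICE/IoU identity", {
  set.seed(33)
  n <- 50
  P <- randomBoxes(n); G <- randomBoxes(n)
  rec <- evaluateDetections(P, G, sample(c("basal", "middle", "apical"), n,
                                         replace = TRUE))
  expect_equal(rec$dice, 2 * rec$iou / (1 + rec$iou), tolerance = 1e-9)
  expect_true(all(rec$iou >= 0 & rec$iou <= rec$dice & rec$dice <= 1))
})

test_that("aggregation pools records per slice and globally", {
  rec <- data.frame(
    image_id = sprintf("i%02d", 1:4),
    slice_type = c("basal", "basal", "apical", "apical"),
    iou = c(0.6, 0.6, 0.4, 0.2), dice = c(0.75, 0.75, 0.57, 0.33),
    eps_cp_a = c(5, 5, 8, 10), eps_cp_epi = c(0.2, 0.2, 0.4, 0.5),
    eps_cp_endo = c(0.3, 0.3, 0.5, 0.6),
    cir_hit = c(TRUE, TRUE, FALSE, FALSE))
  s <- aggregateMetrics(rec)
  expect_equal(s$slice, c("basal", "apical", "Global"))
  basal <- s[s$slice == "basal", ]
  expect_equal(basal$iou_mean, 0.6)
  expect_equal(basal$iou_sd, 0)               # identical records
  expect_equal(basal$cir_mean, 1)
  glob <- s[s$slice == "Global", ]
  expect_equal(glob$cir_mean, 0.5)            # 2 hits of 4
  expect_equal(glob$iou_mean, mean(rec$iou))  # pooled, not slice-averaged
  expect_equal(glob$iou_sd, sd(rec$iou))
  expect_equal(glob$n, 4L)
  # permutation invariance
  s2 <- aggregateMetrics(rec[sample(4), ])
  expect_equal(s2[order(s2$slice), ], s[order(s$slice), ],
               ignore_attr = TRUE)
  bad <- rec; bad$slice_type[1] <- "mid"
  expect_error(aggregateMetrics(bad), "unknown slice")
})
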