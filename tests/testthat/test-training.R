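test_that("1-DICE box loss matches area counting and stays in [0, 1]", {
  expect_equal(diceBoxLoss(c(0.2, 0.2, 0.7, 0.6), c(0.2, 0.2, 0.7, 0.6)), 0,
               tolerance = 1e-6)
  expect_equal(diceBoxLoss(c(0, 0, 0.2, 0.2), c(0.5, 0.5, 0.9, 0.9)), 1)
  # pixel-unit oracle: boxes (0,0,2,2) and (1,1,3,3) overlap in 1 of 4+4
  expect_equal(diceBoxLoss(c(0, 0, 2, 2), c(1, 1, 3, 3)), 0.75,
               tolerance = 1e-7)
  set.seed(11)
  for (i in 1:200) {
    pred <- rnorm(4); gt <- randomBoxes(1)[1, ]
    l <- diceBoxLoss(pred, gt)
    expect_true(l >= 0 && l <= 1)
  }
})

test_that("loss equals 1 - DICE and 1 - 2J/(1+J) of the same boxes", {
  set.seed(12)
  P <- randomBoxes(100); G <- randomBoxes(100)
  for (i in 1:100) {
    J <- boxIoU(P[i, ], G[i, ])
    # equal up to the 1e-7 denominator guard of the loss
    expect_equal(diceBoxLoss(P[i, ], G[i, ]), 1 - boxDice(P[i, ], G[i, ]),
                 tolerance = 1e-4)
    expect_equal(diceBoxLoss(P[i, ], G[i, ]), 1 - 2 * J / (1 + J),
                 tolerance = 1e-4)
  }
})

test_that("loss gradient matches finite differences", {
  set.seed(13)
  for (i in 1:50) {
    pred <- matrix(runif(4, -0.2, 1.2), 1)
    gt <- randomBoxes(1, minEdge = 0.1)
    ana <- ViTLV:::diceBoxLossBatch(pred, gt)$grad
    for (j in 1:4) {
      eps <- 1e-6
      up <- pred; up[j] <- up[j] + eps
      dn <- pred; dn[j] <- dn[j] - eps
      num <- (ViTLV:::diceBoxLossBatch(up, gt)$loss -
                ViTLV:::diceBoxLossBatch(dn, gt)$loss) / (2 * eps)
      # skip kink points of the clamped geometry
      if (abs(num - ana[j]) > 1e-4)
        expect_true(abs(up[j] - gt[j]) < 2e-6 || abs(dn[j] - gt[j]) < 2e-6 ||
                      abs(up[1] - up[3]) < 2e-6 || abs(up[2] - up[4]) < 2e-6)
      else expect_equal(num, ana[j], tolerance = 1e-4)
    }
  }
})

test_that("zero shift is the identity and shifts move box and pixels together", {
  x <- array(rnorm(40 * 40 * 2), c(40, 40, 2))
  box <- boundingBox(0.3, 0.3, 0.6, 0.7)
  set.seed(14)
  out0 <- randomShiftAugment(x, box, shiftRange = 0L)
  expect_identical(out0$image, x)
  expect_equal(corners(out0$box), corners(box))
  # a known shift: +5 columns moves x-corners by 5/C exactly
  shifted <- ViTLV:::translateStack(x, 0L, 5L)
  expect_identical(shifted[, 6:40, ], x[, 1:35, ])
  expect_true(all(shifted[, 1:5, ] == 0))
  for (i in 1:50) {
    out <- randomShiftAugment(x, box, shiftRange = 8L)
    co <- corners(out$box)
    expect_equal(unname(co["x1"]), 0.3 + out$shift[["dx"]] / 40)
    expect_equal(unname(co["y2"]), 0.7 + out$shift[["dy"]] / 40)
  }
  expect_error(randomShiftAugment(x, box, shiftRange = 30L), "half")
})

test_that("shift draws are uniform over the integer range", {
  x <- array(0, c(100, 100, 1))
  box <- boundingBox(0.4, 0.4, 0.6, 0.6)  # never rejected at range 20
  set.seed(15)
  dx <- vapply(1:10000, function(i)
    randomShiftAugment(x, box, shiftRange = 20L)$shift[["dx"]], numeric(1))
  expect_true(all(dx %in% -20:20))
  p <- chisq.test(tabulate(dx + 21, 41))$p.value
  expect_gt(p, 0.001)
})

test_that("subject-grouped splits reproduce the cohort bookkeeping", {
  ids <- sprintf("s%03d", 1:530)
  plan <- makeSplits(ids, testFrac = 0.2, valFrac = 0.1, k = 5, seed = 1)
  for (f in plan@folds) {
    expect_length(f$test, 106)        # 318 images at 3 slices each
    expect_length(f$validation, 43)   # 129 images
    expect_length(f$train, 381)       # 1143 images
    expect_length(intersect(f$train, f$test), 0)
    expect_length(intersect(f$train, f$validation), 0)
    expect_length(intersect(f$validation, f$test), 0)
  }
  tests <- unlist(lapply(plan@folds, `[[`, "test"))
  expect_false(anyDuplicated(tests) > 0)
  expect_setequal(tests, ids)
  expect_error(makeSplits(ids, testFrac = 0.6, valFrac = 0.5), "below 1")
  expect_error(makeSplits(c(ids, ids[1])), "unique")
})

test_that("all slices of a subject land in one partition", {
  co <- simulateCohort(10, imageRows = 64, seed = 16)
  data <- detectionDataset(co)
  plan <- makeSplits(unique(data$index$subject_id), k = 5, seed = 2)
  for (f in plan@folds) {
    part <- ifelse(data$index$subject_id %in% f$train, "train",
                   ifelse(data$index$subject_id %in% f$validation, "val",
                          "test"))
    bysub <- tapply(part, data$index$subject_id,
                    function(p) length(unique(p)))
    expect_true(all(bysub == 1L))
  }
})

test_that("the learning-rate schedule decays exponentially", {
  cfg <- trainConfig()
  expect_equal(scheduledLr(cfg, 0), 1e-4)
  expect_equal(scheduledLr(cfg, 100000), 9.6e-5)
  expect_equal(scheduledLr(cfg, 50000), 1e-4 * 0.96^0.5)
})

test_that("training loss strictly decreases on noiseless phantoms", {
  co <- simulateCohort(20, imageRows = 64, noiseSigma = 0, seed = 21)
  data <- detectionDataset(co)
  model <- vitModel(reducedNoDropConfig(), seed = 22)
  cfg <- trainConfig(batchSize = 48, maxEpochs = 5, initialLr = 1e-3,
                     shiftRange = 0L, seed = 23)
  fit <- trainDetector(model, data, 1:48, 49:60, cfg)
  expect_true(all(diff(fit$history$trainLoss) < 0))
  expect_equal(nrow(fit$history), 5L)
  expect_true(fit$bestEpoch >= 1 && fit$bestEpoch <= 5)
})

test_that("identical seeds reproduce the loss trace exactly", {
  co <- simulateCohort(6, imageRows = 64, seed = 24)
  data <- detectionDataset(co)
  cfg <- trainConfig(batchSize = 8, maxEpochs = 2, initialLr = 1e-3,
                     shiftRange = 3L, seed = 25)
  run <- function() {
    model <- vitModel(reducedViTConfig(), seed = 26)
    trainDetector(model, data, 1:14, 15:18, cfg)$history
  }
  expect_identical(run(), run())
})
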