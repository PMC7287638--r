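test_that("model shapes follow the architecture arithmetic", {
  aug <- buildDualModel(dualModelConfig("cnn_aug", seed = 1))
  expect_equal(layerShapes(aug)$flatten, 3200L)   # 42 -> 21 -> 10, x32
  noaug <- buildDualModel(dualModelConfig("cnn_noaug", seed = 1))
  expect_equal(layerShapes(noaug)$flatten, 128L)  # 10 -> 5 -> 2, x32
  expect_equal(ncol(aug@params$Whc), 5L)          # 5-way classification head
  expect_equal(ncol(aug@params$Whr), 1L)          # 1-way regression head
  gru <- buildDualModel(dualModelConfig("gru", seed = 1))
  expect_equal(layerShapes(gru)$units, 32L)
  expect_equal(dim(gru@params$Wz), c(10L, 32L))
  expect_error(dualModelConfig("cnn_aug", epochs = 0), "epochs")
})

test_that("prediction returns calibrated probabilities and argmax labels", {
  cfg <- dualModelConfig("cnn_noaug", seed = 2)
  model <- buildDualModel(cfg)
  imgs <- array(rnorm(10 * 10 * 7), c(10, 10, 7))
  pr <- predictDual(model, imgs)
  expect_equal(dim(pr$probabilities), c(7L, 5L))
  expect_equal(rowSums(pr$probabilities), rep(1, 7), tolerance = 1e-6)
  expect_true(all(pr$probabilities > 0 & pr$probabilities < 1))
  expect_equal(pr$labels,
               max.col(pr$probabilities, ties.method = "first") - 1L)
  expect_error(predictDual(model, array(0, c(9, 9, 2))), "shape")
})

test_that("tied probabilities resolve to the lowest class index", {
  p <- rbind(c(0.3, 0.3, 0.2, 0.1, 0.1))
  expect_equal(max.col(p, ties.method = "first") - 1L, 0L)
})

# small shared training fixture: one noiseless subject, two short trials
.modelFixture <- function() {
  cfg <- tinyConfig(noiseSd = 0, driftSd = 0, secondsPerFinger = 2)
  ds <- simulateDataset(cfg)
  std <- fitStandardizer(trials(ds))
  arr <- buildArrangement(10, "identity")
  makeImageDataset(trials(ds), arr, windowLen = 10, standardizer = std,
                   concatMode = "paper")
}

test_that("training is reproducible and its loss decreases", {
  imgs <- .modelFixture()
  cfg <- dualModelConfig("cnn_noaug", epochs = 6, seed = 7)
  m1 <- trainDualModel(imgs, cfg)
  m2 <- trainDualModel(imgs, cfg)
  expect_identical(m1@history, m2@history)
  expect_identical(predictDual(m1, imgs)$angles,
                   predictDual(m2, imgs)$angles)
  h <- m1@history$total
  expect_lt(h[length(h)], h[1])
  # monotone trend up to 5% single-epoch jitter
  expect_true(all(diff(h) <= 0.05 * h[-length(h)]))
})

test_that("trainer-reported losses equal the standalone loss functions", {
  imgs <- .modelFixture()
  cfg <- dualModelConfig("cnn_noaug", epochs = 2, seed = 7)
  model <- trainDualModel(imgs, cfg)
  # full-pass forward loss, recomputed by the exported loss functions
  pr <- predictDual(model, imgs)
  hot <- fmgdual:::.oneHot(gestureLabels(imgs), 5)
  cer <- crossEntropyLoss(hot, pr$probabilities)
  mser <- mseLoss(jointAngles(imgs), pr$angles)
  dl <- dualLoss(model, imgs)
  expect_equal(dl$ce, cer, tolerance = 1e-12)
  expect_equal(dl$mse, mser, tolerance = 1e-12)
  expect_equal(dl$total, totalLoss(cer, mser, cfg@wC, cfg@wR),
               tolerance = 1e-12)
  # and the compiled training step reports the same joint loss on a batch
  geom <- fmgdual:::.modelGeom(model)
  idx <- 1:32
  Xb <- fmgdual:::.imagesToBatch(images(imgs)[, , idx, drop = FALSE])
  res <- fmgdual:::.cnnLossGrad(model@params, Xb, 32L,
                                hot[idx, ], jointAngles(imgs)[idx], cfg,
                                geom)
  fw <- predictDual(model, images(imgs)[, , idx, drop = FALSE])
  expect_equal(res$lossC, crossEntropyLoss(hot[idx, ], fw$probabilities),
               tolerance = 1e-5)
  expect_equal(res$lossR, mseLoss(jointAngles(imgs)[idx], fw$angles),
               tolerance = 1e-5)
  expect_equal(res$loss, cfg@wC * res$lossC + cfg@wR * res$lossR,
               tolerance = 1e-12)
})

test_that("a classification-only weighting still trains the classifier", {
  imgs <- .modelFixture()
  cfg <- dualModelConfig("cnn_noaug", epochs = 6, wR = 0, seed = 7)
  model <- trainDualModel(imgs, cfg)
  pr <- predictDual(model, imgs)
  expect_gt(accuracy(pr$labels, gestureLabels(imgs)), 0.8)
  expect_equal(model@history$total, model@history$ce, tolerance = 1e-12)
})

test_that("joint training stays within 2 points of classification-only", {
  # held-out-trial comparison for the augmented model: the multi-task
  # head sharing must not degrade the classifier
  cfg <- tinyConfig(nTrialsPerSubject = 3, noiseSd = 0, driftSd = 0,
                    secondsPerFinger = 2)
  tl <- trials(simulateDataset(cfg))
  std <- fitStandardizer(tl[1:2])
  arr <- buildArrangement(10, "paper_fixture")
  trainImgs <- makeImageDataset(tl[1:2], arr, standardizer = std)
  testImgs <- makeImageDataset(tl[3], arr, standardizer = std)
  joint <- trainDualModel(trainImgs, dualModelConfig("cnn_aug", seed = 11))
  clsOnly <- trainDualModel(trainImgs, dualModelConfig("cnn_aug", wR = 0,
                                                       seed = 11))
  accJ <- accuracy(predictDual(joint, testImgs)$labels,
                   gestureLabels(testImgs))
  accC <- accuracy(predictDual(clsOnly, testImgs)$labels,
                   gestureLabels(testImgs))
  expect_gte(accJ, accC - 0.02)
})

test_that("the GRU exposes the same predict contract as the CNNs", {
  imgs <- .modelFixture()
  cfg <- dualModelConfig("gru", epochs = 3, seed = 7)
  model <- trainDualModel(imgs, cfg)
  pr <- predictDual(model, imgs)
  expect_named(pr, c("probabilities", "labels", "angles"))
  expect_equal(rowSums(pr$probabilities), rep(1, length(imgs)),
               tolerance = 1e-6)
  expect_gt(accuracy(pr$labels, gestureLabels(imgs)), 0.5)
  m2 <- trainDualModel(imgs, cfg)
  expect_identical(m2@history, model@history)
})

test_that("models survive a save/load round trip with history CSV", {
  imgs <- .modelFixture()
  model <- trainDualModel(imgs, dualModelConfig("cnn_noaug", epochs = 2,
                                                seed = 3))
  f <- tempfile(fileext = ".rds")
  saveDualModel(model, f)
  back <- loadDualModel(f)
  expect_identical(back@params, model@params)
  hist <- read.csv(paste0(f, ".history.csv"))
  expect_equal(hist$total, model@history$total)
  unlink(c(f, paste0(f, ".history.csv")))
})

test_that("empty or mislabelled datasets are rejected", {
  imgs <- .modelFixture()
  cfg <- dualModelConfig("cnn_noaug", epochs = 1, nClasses = 3, seed = 1)
  expect_error(trainDualModel(imgs, cfg), "labels")
  expect_error(trainDualModel(imgs[integer(0)],
                              dualModelConfig("cnn_noaug")), "empty")
})
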