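test_that("window slicing yields Ls - w windows ending at the last sample", {
  x <- matrix(seq_len(100 * 2), 100, 2)
  sw <- sliceWindows(x, 42)
  expect_equal(dim(sw$windows), c(42L, 2L, 58L))
  expect_equal(sw$starts, 1:58)
  expect_equal(sw$windows[, , 58], unname(x[59:100, ]))  # last row included
  expect_equal(sw$windows[, , 1], unname(x[2:43, ]))
  one <- sliceWindows(matrix(1:43, ncol = 1), 42)
  expect_equal(dim(one$windows)[3], 1L)
  expect_equal(drop(one$windows), 2:43)
  expect_error(sliceWindows(matrix(1:42, ncol = 1), 42), "insufficient")
})

test_that("windows are bit-identical row slices of the source", {
  set.seed(8)
  x <- matrix(rnorm(300), 60, 5)
  sw <- sliceWindows(x, 13)
  for (k in c(1, 20, 47))
    expect_identical(sw$windows[, , k],
                     unname(x[(sw$starts[k] + 1):(sw$starts[k] + 13), ]))
})

test_that("window targets use the modal label and last-step angle", {
  expect_equal(assignTargets(rep(3L, 42), seq(36, 77, length.out = 42)),
               list(label = 3L, angleTarget = 77))
  labs <- c(rep(1L, 20), rep(2L, 22))
  expect_equal(assignTargets(labs, seq_along(labs))$label, 2L)
  tie <- c(rep(1L, 21), rep(2L, 21))
  expect_equal(assignTargets(tie, seq_along(tie))$label, 2L)  # later run wins
  tieRev <- c(rep(2L, 21), rep(1L, 21))
  expect_equal(assignTargets(tieRev, seq_along(tieRev))$label, 1L)
  expect_error(assignTargets(integer(0), numeric(0)), "invalid input")
})

test_that("standardizer fits population statistics and round-trips", {
  tr <- new("FmgTrial", subjectId = "S", trialId = "T",
            pressures = cbind(c(2, 4), c(10, 10)), labels = c(0L, 1L),
            angles = c(10, 30), sampleRate = 40)
  expect_warning(std <- fitStandardizer(list(tr)), "zero-variance")
  expect_equal(std@channelMean, c(3, 10))
  expect_equal(std@channelSd, c(1, 1))          # population sd; guard on ch2
  s <- applyStandardizer(tr, std)
  expect_equal(sensorData(s)[, 1], c(-1, 1))
  expect_equal(sensorData(s)[, 2], c(0, 0))     # guarded constant channel
  expect_equal(unstandardizeAngles(jointAngles(s), std), c(10, 30),
               tolerance = 1e-9)
})

test_that("standardized training channels have mean 0 and sd 1", {
  cfg <- tinyConfig()
  tr <- simulateTrial(cfg, 1, 1)
  std <- fitStandardizer(list(tr))
  s <- sensorData(applyStandardizer(tr, std))
  expect_lt(max(abs(colMeans(s))), 1e-9)
  n <- nrow(s)
  popSd <- sqrt(colSums(sweep(s, 2, colMeans(s))^2) / n)
  expect_lt(max(abs(popSd - 1)), 1e-9)
})

test_that("sample-convention standard deviation is available", {
  tr <- new("FmgTrial", subjectId = "S", trialId = "T",
            pressures = cbind(c(2, 4, 6), c(1, 5, 9)),
            labels = c(0L, 1L, 2L), angles = c(0, 1, 2), sampleRate = 40)
  std <- fitStandardizer(list(tr), sdConvention = "sample")
  expect_equal(std@channelSd, c(sd(c(2, 4, 6)), sd(c(1, 5, 9))))
})

test_that("image dataset counts follow the concatenation mode", {
  cfg <- tinyConfig(nTrialsPerSubject = 3, secondsPerFinger = 1)  # T = 200
  ds <- simulateDataset(cfg)
  arr <- buildArrangement(10, "paper_fixture")
  paper <- makeImageDataset(trials(ds), arr, concatMode = "paper")
  expect_equal(length(paper), 3L * 200L - 42L)
  per <- makeImageDataset(trials(ds), arr, concatMode = "per_trial")
  expect_equal(length(per), 3L * (200L - 42L))
  expect_equal(dim(images(per))[1:2], c(42L, 42L))
  # per-trial windows never cross trials
  expect_true(all(table(provenance(per)$trialId) == 158L))
})

test_that("image datasets are byte-identical across rebuilds", {
  cfg <- tinyConfig()
  ds <- simulateDataset(cfg)
  arr <- buildArrangement(10, "pair_complete")
  a <- makeImageDataset(trials(ds), arr, windowLen = 50)
  b <- makeImageDataset(trials(ds), arr, windowLen = 50)
  expect_identical(images(a), images(b))
  expect_identical(gestureLabels(a), gestureLabels(b))
  expect_identical(jointAngles(a), jointAngles(b))
})

test_that("images carry provenance and standardized last-step targets", {
  cfg <- tinyConfig(nTrialsPerSubject = 2, secondsPerFinger = 1)
  ds <- simulateDataset(cfg)
  std <- fitStandardizer(trials(ds))
  arr <- buildArrangement(10, "identity")
  imgs <- makeImageDataset(trials(ds), arr, windowLen = 10,
                           standardizer = std, concatMode = "per_trial")
  pv <- provenance(imgs)
  expect_named(pv, c("subjectId", "trialId", "start"))
  k <- 25L
  tr <- trials(ds)[[1]]
  lastRow <- pv$start[k] + 10L
  expect_equal(jointAngles(imgs)[k],
               standardizeAngles(jointAngles(tr)[lastRow], std))
  expect_error(makeImageDataset(trials(ds), buildArrangement(4, "identity")),
               "shape")
})

test_that("image sets survive a serialization round trip", {
  cfg <- tinyConfig()
  imgs <- makeImageDataset(list(simulateTrial(cfg, 1, 1)),
                           buildArrangement(10, "identity"))
  f <- tempfile(fileext = ".rds")
  writeImageSet(imgs, f)
  back <- readImageSet(f)
  expect_identical(images(back), images(imgs))
  expect_identical(provenance(back), provenance(imgs))
  unlink(f)
})
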