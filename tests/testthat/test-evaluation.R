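test_that("leave-one-trial-out folds partition the trials", {
  cfg <- tinyConfig(nTrialsPerSubject = 10)
  ds <- simulateDataset(cfg)
  folds <- lotoFolds(trials(ds))
  expect_length(folds, 10L)
  testIds <- vapply(folds, `[[`, character(1), "testTrialId")
  expect_setequal(testIds, vapply(trials(ds), trialId, character(1)))
  expect_false(anyDuplicated(testIds) > 0)
  for (f in folds) {
    expect_length(f$train, 9L)
    expect_false(f$testTrialId %in% vapply(f$train, trialId, character(1)))
  }
  two <- lotoFolds(trials(ds)[1:2])
  expect_length(two, 2L)
  expect_length(two[[1]]$train, 1L)
  expect_error(lotoFolds(list(ds[[1]], ds[[1]])), "duplicate")
  expect_error(lotoFolds(trials(ds)[1]), "at least 2")
})

test_that("accuracy, R2 and confusion match their definitions", {
  expect_equal(accuracy(c(0, 1, 2, 2), c(0, 1, 2, 3)), 0.75)
  expect_equal(accuracy(1:5, 1:5), 1)
  expect_equal(accuracy(1:5, 6:10), 0)
  expect_equal(rSquared(c(0, 1, 2), c(0, 0, 3)), 0)
  y <- rnorm(20)
  expect_equal(rSquared(y, y), 1)
  expect_equal(rSquared(y, rep(mean(y), 20)), 0)
  # invariant under a common affine map
  yh <- y + rnorm(20, 0, 0.3)
  expect_equal(rSquared(y, yh), rSquared(3 * y - 2, 3 * yh - 2))
  expect_error(rSquared(rep(1, 5), rnorm(5)), "zero-variance")
  cm <- confusionMatrix(c(1L, 1L), c(0L, 1L), 5)
  expect_equal(cm[1, 2], 1)
  expect_equal(cm[2, 2], 1)
  expect_equal(sum(cm), 2)
  perfect <- confusionMatrix(0:4, 0:4, 5)
  expect_equal(perfect, diag(5), ignore_attr = TRUE)
  rowpct <- confusionMatrix(c(0L, 0L, 1L, 1L), c(0L, 0L, 0L, 1L), 2,
                            normalize = TRUE)
  expect_equal(rowpct[1, ], c(66.6667, 33.3333),
               tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("metrics agree with naive loop oracles on random instances", {
  set.seed(11)
  for (rep in 1:100) {
    n <- sample(2:50, 1)
    k <- sample(2:6, 1)
    pred <- sample(0:(k - 1), n, TRUE)
    true <- sample(0:(k - 1), n, TRUE)
    expect_equal(accuracy(pred, true), naiveAccuracy(pred, true),
                 tolerance = 1e-12)
    expect_equal(confusionMatrix(pred, true, k),
                 naiveConfusion(pred, true, k), ignore_attr = TRUE)
    y <- rnorm(n) + seq_len(n)        # guaranteed variance
    yh <- rnorm(n)
    expect_equal(rSquared(y, yh), naiveR2(y, yh), tolerance = 1e-12)
  }
})

test_that("signed-rank p-values are exact", {
  a <- c(0.97, 0.96, 0.98, 0.95, 0.97, 0.99, 0.96, 0.97, 0.98, 0.955)
  res <- pairedSignedRankTest(a, a - seq(0.01, 0.055, length.out = 10))
  expect_equal(res@statistic, 55)           # all differences positive
  expect_equal(res@pValue, 2 / 1024, tolerance = 1e-12)
  expect_true(res@significant)
  # swapping the groups mirrors the statistic and keeps p
  swapped <- pairedSignedRankTest(a - seq(0.01, 0.055, length.out = 10), a)
  expect_equal(swapped@statistic, 0)
  expect_equal(swapped@pValue, res@pValue, tolerance = 1e-12)
  expect_error(pairedSignedRankTest(a, a), "degenerate")
})

test_that("signed-rank p matches brute-force enumeration and wilcox.test", {
  set.seed(12)
  for (rep in 1:20) {
    m <- sample(5:10, 1)
    a <- rnorm(m)
    b <- rnorm(m)
    res <- pairedSignedRankTest(a, b)
    expect_equal(res@pValue, naiveSignedRankP(a, b), tolerance = 1e-12)
    wt <- suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = TRUE))
    if (!anyDuplicated(abs(a - b)))
      expect_equal(res@pValue, wt$p.value, tolerance = 1e-12)
  }
  # zero differences are dropped with their count recorded
  a <- c(1, 2, 3, 4, 5, 6)
  b <- c(1, 2, 2.5, 3.1, 4.4, 5.2)
  res <- pairedSignedRankTest(a, b)
  expect_equal(res@nZeroDropped, 2L)
})

test_that("an experiment runs every fold once and summarises by subject", {
  ds <- oracleDataset(nSubjects = 2, nTrials = 3)
  res <- runExperiment(ds, model = "rf",
                       shallowCfg = shallowConfig(rfClsTrees = 20,
                                                  rfRegTrees = 20),
                       seed = 4)
  expect_equal(nrow(res@perFold), 6L)
  expect_equal(nrow(res@subjectSummary), 2L)
  expect_equal(sum(res@confusion), sum(res@perFold$nTest))
  expect_equal(res@grandAccuracy, mean(res@subjectSummary$accuracy))
  # informative-channel oracle data: far above the 0.2 chance level even
  # though near-rest samples are inherently ambiguous
  expect_gt(res@grandAccuracy, 0.5)
  # reruns reproduce the summary exactly
  res2 <- runExperiment(ds, model = "rf",
                        shallowCfg = shallowConfig(rfClsTrees = 20,
                                                   rfRegTrees = 20),
                        seed = 4)
  expect_identical(res2@perFold, res@perFold)
})

test_that("grand means do not depend on trial ordering", {
  ds <- oracleDataset(nSubjects = 2, nTrials = 3)
  shuffled <- new("FmgDataset", trials = rev(trials(ds)), simConfig = NULL)
  cfgS <- shallowConfig(rfClsTrees = 15, rfRegTrees = 15)
  r1 <- runExperiment(ds, model = "rf", shallowCfg = cfgS, seed = 4)
  r2 <- runExperiment(shuffled, model = "rf", shallowCfg = cfgS, seed = 4)
  expect_equal(r1@grandAccuracy, r2@grandAccuracy, tolerance = 1e-12)
  expect_equal(r1@grandR2, r2@grandR2, tolerance = 1e-12)
})

test_that("no fold leaks its test trial into fitting", {
  ds <- oracleDataset(nSubjects = 1, nTrials = 3)
  res <- runExperiment(ds, model = "svm", concatMode = "per_trial",
                       seed = 2)
  audit <- auditLeakage(res)
  expect_true(attr(audit, "clean"))
  expect_true(all(audit$stdClean))
  expect_true(all(audit$windowsClean))
})

test_that("mismatched trial counts per subject are rejected", {
  tr <- c(trials(oracleDataset(1, 3)), trials(oracleDataset(2, 2))[3:4])
  ds <- new("FmgDataset", trials = tr, simConfig = NULL)
  expect_error(runExperiment(ds, model = "rf"), "same trial count")
})

test_that("sensor ablation restricts channels along the ranking", {
  ds <- oracleDataset(nSubjects = 1, nTrials = 3)
  imp <- computeImportance(ds, shallowConfig(seed = 7))
  tab <- sensorAblation(ds, imp, kRange = c(1L, 2L, 6L), model = "rf",
                        shallowCfg = shallowConfig(rfClsTrees = 20,
                                                   rfRegTrees = 20),
                        seed = 3)
  expect_equal(tab$k, c(1L, 2L, 6L))
  chans <- attr(tab, "channels")
  expect_equal(lengths(chans), c(1L, 2L, 6L))
  expect_equal(chans[[2]], selectTopK(imp, 2))
  # both informative channels beat the single best channel on oracle data
  expect_gt(tab$accuracy[tab$k == 2], tab$accuracy[tab$k == 1])
  expect_gte(tab$accuracy[tab$k == 6], tab$accuracy[tab$k == 1])
})
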