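test_that("angle trajectory spans [0, amplitude] over whole periods", {
  th <- angleTrajectory(0, duration = 2, sampleRate = 40, amplitude = 55,
                        freq = 0.5)
  expect_equal(max(th), 55)
  expect_equal(min(th), 0)
  expect_equal(th[1], 0)                       # phase 0 at t = 0
  th90 <- angleTrajectory(1, duration = 2, sampleRate = 40,
                          amplitude = 90, freq = 0.5)
  expect_equal(th90[41], 90)                   # t = 1 s is the peak
  expect_error(angleTrajectory(0, -1, 40, 55, 0.5), "invalid config")
  expect_error(angleTrajectory(0, 2, 0, 55, 0.5), "invalid config")
  expect_error(angleTrajectory(0, 2, 40, 55, -0.5), "invalid config")
})

test_that("sensor response is baseline at rest and deterministic", {
  cp <- matrix(runif(50), 10, 5)
  bl <- runif(10)
  ang0 <- matrix(0, 30, 5)
  p <- sensorResponse(ang0, cp, bl, noiseSd = 0, driftSd = 0)
  expect_equal(p, matrix(bl, 30, 10, byrow = TRUE))
  angs <- matrix(runif(150, 0, 90), 30, 5)
  p1 <- sensorResponse(angs, cp, bl, noiseSd = 0.1, driftSd = 0.01,
                       seed = 7)
  p2 <- sensorResponse(angs, cp, bl, noiseSd = 0.1, driftSd = 0.01,
                       seed = 7)
  expect_identical(p1, p2)
  expect_error(sensorResponse(angs[, 1:4], cp, bl), "shape")
})

test_that("coupling is recoverable from a noiseless response by least squares", {
  set.seed(1)
  cp <- matrix(runif(50, 0.1, 1), 10, 5)
  bl <- runif(10)
  amp <- c(55, 90, 90, 90, 90)
  angs <- matrix(runif(500, 0, 1), 100, 5) %*% diag(amp)
  p <- sensorResponse(angs, cp, bl, noiseSd = 0, driftSd = 0,
                      amplitudePerFinger = amp)
  g <- fmgdual:::.saturate(sweep(angs, 2, amp, "/"))
  est <- t(qr.solve(g, sweep(p, 2, bl)))
  expect_lt(max(abs(est - cp)), 1e-6)
})

test_that("a default trial has the protocol's shape and label layout", {
  cfg <- simConfig(nSubjects = 1, nTrialsPerSubject = 1, seed = 3)
  tr <- simulateTrial(cfg, 1, 1)
  expect_equal(nSamples(tr), 1000L)
  expect_equal(nChannels(tr), 10L)
  expect_equal(gestureLabels(tr), rep(0:4, each = 200L))
  amp <- cfg@amplitudePerFinger[gestureLabels(tr) + 1L]
  expect_true(all(jointAngles(tr) >= 0 & jointAngles(tr) <= amp))
})

test_that("trial length follows seconds x rate x 5 fingers exactly", {
  cfg <- simConfig(nSubjects = 1, nTrialsPerSubject = 1,
                   secondsPerFinger = 2, sampleRate = 25, seed = 3)
  expect_equal(nSamples(simulateTrial(cfg, 1, 1)), 2L * 25L * 5L)
  expect_error(simConfig(secondsPerFinger = 0.33, sampleRate = 40),
               "integer")
})

test_that("datasets have the full factorial size and are reproducible", {
  cfg <- tinyConfig(nSubjects = 2, nTrialsPerSubject = 3)
  ds <- simulateDataset(cfg)
  expect_equal(length(ds), 6L)
  total <- sum(vapply(trials(ds), nSamples, integer(1)))
  expect_equal(total, 2L * 3L * 5L * 1L * 40L)
  ds2 <- simulateDataset(cfg)
  expect_identical(sensorData(ds[[4]]), sensorData(ds2[[4]]))
  expect_identical(jointAngles(ds[[1]]), jointAngles(ds2[[1]]))
})

test_that("any single trial is reproducible in isolation", {
  cfg <- tinyConfig(nSubjects = 2, nTrialsPerSubject = 3)
  ds <- simulateDataset(cfg)
  lone <- simulateTrial(cfg, 2, 3)
  expect_identical(sensorData(ds[[6]]), sensorData(lone))
})

test_that("subjects differ in coupling but keep it fixed across trials", {
  cfg <- tinyConfig(nSubjects = 2, nTrialsPerSubject = 2)
  s1 <- subjectCoupling(cfg, 1)
  s2 <- subjectCoupling(cfg, 2)
  expect_gt(max(abs(s1$coupling - s2$coupling)), 0.01)
  expect_identical(s1$coupling, subjectCoupling(cfg, 1)$coupling)
})

test_that("finger-specific channel activation patterns are distinct", {
  cfg <- simConfig(seed = 5)
  cp <- subjectCoupling(cfg, 1)$coupling
  strong <- apply(cp, 2, function(col) which(col > 0.5 * max(col)))
  for (f in 1:4)
    for (g in (f + 1):5)
      expect_false(setequal(strong[[f]], strong[[g]]))
})

test_that("noiseless pressures are a pure function of the angles", {
  cfg <- tinyConfig(noiseSd = 0, driftSd = 0)
  t1 <- simulateTrial(cfg, 1, 1)
  subj <- subjectCoupling(cfg, 1)
  # rebuild the response from the stored angles alone
  tl <- nSamples(t1)
  angMat <- matrix(0, tl, 5)
  angMat[cbind(seq_len(tl), gestureLabels(t1) + 1L)] <- jointAngles(t1)
  p <- sensorResponse(angMat, subj$coupling, subj$baseline, 0, 0,
                      amplitudePerFinger = cfg@amplitudePerFinger *
                        subj$amplitudeScale)
  expect_equal(unname(p), unname(sensorData(t1)), tolerance = 1e-12)
})
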