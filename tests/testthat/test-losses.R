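test_that("softmax matches its closed form and invariances", {
  expect_equal(softmax(rep(0, 5)), rep(0.2, 5))
  expect_equal(softmax(log(1:4)), c(0.1, 0.2, 0.3, 0.4))
  z <- rnorm(6)
  expect_equal(softmax(z), softmax(z + 13.7))
  zm <- matrix(rnorm(20), 4, 5)
  expect_equal(rowSums(softmax(zm)), rep(1, 4))
  # stabilised against overflow
  expect_false(any(is.nan(softmax(c(1000, 1001, 999)))))
})

test_that("mseLoss matches hand computations and scales quadratically", {
  expect_equal(mseLoss(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mseLoss(c(0, 2), c(1, 1)), 1)
  y <- rnorm(10); yh <- rnorm(10)
  expect_equal(mseLoss(y, y + 3 * (yh - y)), 9 * mseLoss(y, yh))
  expect_error(mseLoss(1:3, 1:4), "shape")
})

test_that("crossEntropyLoss matches hand computations", {
  oh <- diag(5)
  expect_lt(crossEntropyLoss(oh, oh), 1e-6)       # perfect, up to clipping
  expect_equal(crossEntropyLoss(oh, matrix(0.2, 5, 5)), log(5))
  oh2 <- rbind(c(1, 0), c(0, 1))
  p2 <- rbind(c(0.5, 0.5), c(0.75, 0.25))
  expect_equal(crossEntropyLoss(oh2, p2), 1.5 * log(2))
  expect_error(crossEntropyLoss(oh, matrix(0.2, 4, 5)), "shape")
})

test_that("totalLoss is the weighted sum with the 4:1 default", {
  expect_equal(totalLoss(0.5, 0.25), 1.5)
  expect_equal(totalLoss(0.5, 0.25, wC = 1, wR = 4), 1.5)
  expect_equal(totalLoss(0.7, 9, wC = 1, wR = 0), 0.7)
  expect_equal(totalLoss(0, 0), 0)
})

test_that("losses agree with naive loop oracles on random instances", {
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(2:40, 1)
    k <- sample(2:6, 1)
    p <- softmax(matrix(rnorm(n * k), n, k))
    oh <- fmgdual:::.oneHot(sample(0:(k - 1), n, TRUE), k)
    expect_equal(crossEntropyLoss(oh, p), naiveCrossEntropy(oh, p),
                 tolerance = 1e-12)
    y <- rnorm(n); yh <- rnorm(n)
    expect_equal(mseLoss(y, yh), naiveMse(y, yh), tolerance = 1e-12)
  }
})

numGrad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim = if (is.null(dim(x))) length(x) else dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

test_that("CNN analytic gradients match finite differences", {
  set.seed(42)
  cfg <- dualModelConfig("cnn_aug", inputSide = 6, nClasses = 3, seed = 5)
  model <- buildDualModel(cfg)
  geom <- fmgdual:::.modelGeom(model)
  n <- 3
  X <- matrix(rnorm(36 * n), ncol = 1)
  hot <- fmgdual:::.oneHot(sample(0:2, n, TRUE), 3)
  yr <- rnorm(n)
  params <- model@params
  res <- fmgdual:::.cnnLossGrad(params, X, n, hot, yr, cfg, geom)
  for (nm in names(res$grads)) {
    f <- function(p) {
      pp <- params; pp[[nm]] <- p
      fmgdual:::.cnnLossGrad(pp, X, n, hot, yr, cfg, geom)$loss
    }
    ng <- numGrad(f, params[[nm]])
    expect_lt(max(abs(ng - res$grads[[nm]])) / (max(abs(ng)) + 1e-8),
              1e-6)
  }
})

test_that("GRU analytic gradients match finite differences incl. dropout", {
  set.seed(43)
  cfg <- dualModelConfig("gru", inputSide = 5, inputChannels = 4,
                         nClasses = 3, gruUnits = 6, seed = 5,
                         gruDropout = 0.3, gruRecurrentDropout = 0.3)
  model <- buildDualModel(cfg)
  n <- 3
  X <- array(rnorm(5 * 4 * n), c(5, 4, n))
  hot <- fmgdual:::.oneHot(sample(0:2, n, TRUE), 3)
  yr <- rnorm(n)
  params <- model@params
  masks <- fmgdual:::.gruMasks(n, cfg)
  res <- fmgdual:::.gruLossGrad(params, X, hot, yr, cfg, masks)
  for (nm in names(res$grads)) {
    f <- function(p) {
      pp <- params; pp[[nm]] <- p
      fmgdual:::.gruLossGrad(pp, X, hot, yr, cfg, masks)$loss
    }
    ng <- numGrad(f, params[[nm]])
    expect_lt(max(abs(ng - res$grads[[nm]])) / (max(abs(ng)) + 1e-8),
              1e-6)
  }
})
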