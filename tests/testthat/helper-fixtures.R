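# Shared fixtures: all data is generated in code at test time.

# small, fast simulator configuration (T = 5 * secondsPerFinger * 40)
tinyConfig <- function(...) {
  args <- modifyList(list(nSubjects = 1, nTrialsPerSubject = 2,
                          secondsPerFinger = 1, noiseSd = 0.02,
                          driftSd = 0, seed = 42),
                     list(...))
  do.call(simConfig, args)
}

# Oracle cohort for importance/ablation checks: only channels `informative`
# carry the class/angle signal; every other channel is pure Gaussian noise.
oracleTrial <- function(subjectIdx, trialIdx, nChannels = 6L,
                        informative = c(1L, 2L), segLen = 80L,
                        seed = 99L) {
  set.seed(seed + 1000L * subjectIdx + trialIdx)
  tl <- 5L * segLen
  labels <- rep(0:4, each = segLen)
  angles <- numeric(tl)
  press <- matrix(rnorm(tl * nChannels), tl, nChannels)
  gain1 <- c(0.2, 0.6, 1.0, 1.4, 1.8)
  gain2 <- c(1.8, 1.0, 0.2, 1.4, 0.6)
  for (f in 1:5) {
    rows <- ((f - 1L) * segLen + 1L):(f * segLen)
    th <- angleTrajectory(f - 1L, segLen / 40, 40, 90, 0.5,
                          phase = runif(1, 0, 2 * pi))
    angles[rows] <- th
    press[rows, informative[1]] <- gain1[f] * th / 90 +
      0.05 * rnorm(segLen)
    press[rows, informative[2]] <- gain2[f] * th / 90 +
      0.05 * rnorm(segLen)
  }
  colnames(press) <- paste0("s", seq_len(nChannels))
  new("FmgTrial", subjectId = sprintf("S%02d", subjectIdx),
      trialId = sprintf("T%02d", trialIdx), pressures = press,
      labels = as.integer(labels), angles = angles, sampleRate = 40)
}

oracleDataset <- function(nSubjects = 1L, nTrials = 3L, ...) {
  tr <- list()
  for (s in seq_len(nSubjects))
    for (t in seq_len(nTrials))
      tr[[length(tr) + 1L]] <- oracleTrial(s, t, ...)
  new("FmgDataset", trials = tr, simConfig = NULL)
}

# naive reference implementations used as independent oracles
naiveAccuracy <- function(pred, true) {
  n <- 0
  for (i in seq_along(true)) if (pred[i] == true[i]) n <- n + 1
  n / length(true)
}

naiveR2 <- function(true, pred) {
  ssr <- 0
  sst <- 0
  m <- sum(true) / length(true)
  for (i in seq_along(true)) {
    ssr <- ssr + (true[i] - pred[i])^2
    sst <- sst + (true[i] - m)^2
  }
  1 - ssr / sst
}

naiveConfusion <- function(pred, true, k) {
  cm <- matrix(0, k, k)
  for (i in seq_along(true)) cm[true[i] + 1, pred[i] + 1] <-
      cm[true[i] + 1, pred[i] + 1] + 1
  cm
}

naiveCrossEntropy <- function(oneHot, p, eps = 1e-7) {
  tot <- 0
  for (i in seq_len(nrow(p)))
    for (j in seq_len(ncol(p)))
      tot <- tot + oneHot[i, j] * log(min(max(p[i, j], eps), 1 - eps))
  -tot / nrow(p)
}

naiveMse <- function(y, yhat) {
  tot <- 0
  for (i in seq_along(y)) tot <- tot + (y[i] - yhat[i])^2
  tot / length(y)
}

# exact signed-rank two-sided p by explicit enumeration of all 2^m sign
# assignments (brute force; feasible for m <= 12)
naiveSignedRankP <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  m <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  ws <- signs %*% r
  pLe <- mean(ws <= w + 1e-12)
  pGe <- mean(ws >= w - 1e-12)
  min(1, 2 * min(pLe, pGe))
}

# every unordered pair of distinct channels adjacent somewhere?
coversAllPairs <- function(ch, n) {
  adj <- cbind(ch[-length(ch)], ch[-1])
  for (i in 1:(n - 1))
    for (j in (i + 1):n)
      if (!any((adj[, 1] == i & adj[, 2] == j) |
               (adj[, 1] == j & adj[, 2] == i))) return(FALSE)
  TRUE
}
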