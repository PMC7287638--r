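#' Classification accuracy
#'
#' Proportion of correctly recognised gestures: n_correct / n_total.
#'
#' @param predicted,true equal-length label vectors.
#' @return scalar in [0, 1].
#' @export
accuracy <- function(predicted, true) {
  if (length(predicted) != length(true)) stop("shape error: length mismatch")
  if (!length(true)) stop("invalid input: empty vectors")
  mean(predicted == true)
}

#' Coefficient of determination
#'
#' \code{R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)}. 1 for perfect
#' prediction, 0 for predicting the mean, negative when worse than the
#' mean. Invariant under a common affine transform applied to both truth
#' and prediction, so it is the same on the degree and standardized angle
#' scales.
#'
#' @param true,predicted equal-length numeric vectors; \code{true} must
#'   have positive variance.
#' @return scalar <= 1.
#' @export
rSquared <- function(true, predicted) {
  if (length(true) != length(predicted)) stop("shape error: length mismatch")
  if (length(true) < 2L) stop("invalid input: need at least 2 samples")
  sst <- sum((true - mean(true))^2)
  if (sst <= 0) stop("undefined metric: zero-variance truth")
  1 - sum((true - predicted)^2) / sst
}

#' Confusion matrix
#'
#' Entry (i, j) counts samples of true class i predicted as class j
#' (0-based classes on both axes).
#'
#' @param predicted,true label vectors in 0..K-1.
#' @param nClasses K.
#' @param normalize return row percentages instead of counts.
#' @return K x K matrix; rows = truth, columns = prediction.
#' @export
confusionMatrix <- function(predicted, true, nClasses = 5L,
                            normalize = FALSE) {
  if (length(predicted) != length(true)) stop("shape error: length mismatch")
  if (any(c(predicted, true) < 0L) || any(c(predicted, true) >= nClasses))
    stop("invalid input: labels outside 0..K-1")
  cm <- matrix(0, nClasses, nClasses,
               dimnames = list(true = 0:(nClasses - 1L),
                               predicted = 0:(nClasses - 1L)))
  for (i in seq_along(true))
    cm[true[i] + 1L, predicted[i] + 1L] <- cm[true[i] + 1L, predicted[i] + 1L] + 1
  if (normalize) {
    rs <- rowSums(cm)
    rs[rs == 0] <- 1
    cm <- 100 * cm / rs
  }
  cm
}

#' Leave-one-trial-out folds
#'
#' Every trial of a subject serves exactly once as the test set while the
#' remaining trials form the training set; folds are ordered by trial.
#'
#' @param subjectTrials list of a single subject's [FmgTrial-class]
#'   objects (>= 2, unique trial ids).
#' @return list of folds, each a list with \code{train} (list of trials),
#'   \code{test} (one trial) and \code{testTrialId}.
#' @export
lotoFolds <- function(subjectTrials) {
  ids <- vapply(subjectTrials, trialId, character(1))
  if (anyDuplicated(ids)) stop("invalid input: duplicate trial ids")
  if (length(subjectTrials) < 2L)
    stop("invalid input: need at least 2 trials")
  ord <- order(ids)
  subjectTrials <- subjectTrials[ord]
  ids <- ids[ord]
  lapply(seq_along(subjectTrials), function(k)
    list(train = subjectTrials[-k], test = subjectTrials[[k]],
         testTrialId = ids[k]))
}

#' Exact Wilcoxon signed-rank paired comparison
#'
#' Nonparametric paired comparison of two models' per-subject scores. Zero
#' differences are dropped (classic reduced-sample procedure; the count is
#' recorded), the absolute differences are ranked with average ranks for
#' ties, and W = sum of the ranks of positive differences (A minus B). The
#' two-sided p-value is exact, computed from the full enumeration of the
#' 2^m equiprobable sign assignments (via a rank-sum convolution, valid
#' for any m and identical to brute-force enumeration):
#' \code{p = min(1, 2 * min(P(W <= w), P(W >= w)))}.
#'
#' @param valuesA,valuesB paired per-subject scores (same subjects, same
#'   order).
#' @param modelA,modelB names for reporting.
#' @param alpha significance level (default 0.05).
#' @return a [ComparisonResult-class]. The \code{statistic} slot holds W.
#' @examples
#' a <- c(.97, .96, .98, .95, .97, .99, .96, .97, .98, .96)
#' pairedSignedRankTest(a, a - 0.01)  # all positive: p = 2/1024
#' @export
pairedSignedRankTest <- function(valuesA, valuesB, modelA = "A",
                                 modelB = "B", alpha = 0.05) {
  if (length(valuesA) != length(valuesB))
    stop("shape error: length mismatch")
  d <- valuesA - valuesB
  nz <- d != 0
  nDrop <- sum(!nz)
  d <- d[nz]
  m <- length(d)
  if (m == 0L)
    stop("degenerate test: all paired differences are zero")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  # distribution of W over all 2^m sign assignments; doubled ranks keep
  # the support integral under average (x.5) tie ranks
  r2 <- as.integer(round(2 * r))
  maxS <- sum(r2)
  dist <- numeric(maxS + 1L)   # dist[s + 1] = #assignments with 2W = s
  dist[1L] <- 1
  for (rk in r2) {
    shifted <- c(numeric(rk), dist[seq_len(maxS + 1L - rk)])
    dist <- dist + shifted
  }
  dist <- dist / sum(dist)
  w2 <- as.integer(round(2 * w))
  pLe <- sum(dist[seq_len(w2 + 1L)])
  pGe <- sum(dist[(w2 + 1L):(maxS + 1L)])
  p <- min(1, 2 * min(pLe, pGe))
  new("ComparisonResult", modelA = modelA, modelB = modelB,
      valuesA = valuesA, valuesB = valuesB, statistic = w, pValue = p,
      significant = p < alpha, nZeroDropped = as.integer(nDrop))
}

# per-(subject, fold) model seed, derived as in the simulator
.foldSeed <- function(rootSeed, subjIdx, foldIdx)
  .deriveSeed(rootSeed, subjIdx, foldIdx)

# subset a trial to a channel subset (original column order of `chans`)
.subsetChannels <- function(trial, chans) {
  if (is.null(chans)) return(trial)
  initialize(trial,
             pressures = sensorData(trial)[, chans, drop = FALSE])
}

# arrangement + window for a model on k channels: the augmented CNN uses
# the published fixture at k = 10 and a pair-complete arrangement for
# 2 <= k < 10 (identity at k = 1); the no-augmentation CNN and the GRU use
# the identity arrangement. Window length = arrangement length (square).
.evalArrangement <- function(model, k) {
  if (model == "cnn_aug") {
    if (k == 10L) buildArrangement(10L, "paper_fixture")
    else if (k >= 2L) buildArrangement(k, "pair_complete")
    else buildArrangement(1L, "identity")
  } else buildArrangement(k, "identity")
}

#' Run a leave-one-trial-out experiment
#'
#' The full evaluation protocol: per subject, each trial is held out once;
#' the standardizer is fitted on the fold's 9 (in general n-1) training
#' trials only and applied to both splits; the model is trained on the
#' training split and scored on the held-out trial (accuracy over all its
#' test images/samples, R-squared of the angle predictions); subject
#' scores are unweighted fold means, and the grand mean / across-subject
#' standard deviation summarise the cohort.
#'
#' Deep models (\code{cnn_aug}, \code{cnn_noaug}, \code{gru}) train on
#' movement images; in \code{concatMode = "paper"} the training trials are
#' concatenated along time before windowing. Shallow models (\code{svm} =
#' SVC + SVR, \code{rf} = RF classifier + regressor) train on raw
#' standardized per-time-step sensor vectors.
#'
#' @param dataset an [FmgDataset-class] (every subject the same trial
#'   count).
#' @param model \code{"cnn_aug"}, \code{"cnn_noaug"}, \code{"gru"},
#'   \code{"svm"} or \code{"rf"}.
#' @param channels optional channel subset (original indices) to restrict
#'   the sensors, e.g. from [selectTopK()].
#' @param dualConfig template [DualModelConfig-class] for deep models;
#'   its architecture/input shape/seed are overridden per fold. NULL uses
#'   defaults.
#' @param shallowCfg [shallowConfig()] list for shallow models.
#' @param concatMode \code{"paper"} or \code{"per_trial"} (training-split
#'   windowing; the test trial is always windowed alone).
#' @param nClasses number of gesture classes.
#' @param seed root seed for per-fold model seeds.
#' @return an [ExperimentResult-class].
#' @export
runExperiment <- function(dataset,
                          model = c("cnn_aug", "cnn_noaug", "gru", "svm",
                                    "rf"),
                          channels = NULL, dualConfig = NULL,
                          shallowCfg = shallowConfig(),
                          concatMode = c("paper", "per_trial"),
                          nClasses = 5L, seed = 1L) {
  model <- match.arg(model)
  concatMode <- match.arg(concatMode)
  bySubj <- splitBySubject(dataset)
  bySubj <- bySubj[order(names(bySubj))]  # subject-order invariance
  nTrials <- vapply(bySubj, length, integer(1))
  if (length(unique(nTrials)) != 1L)
    stop("every subject must have the same trial count")
  deep <- model %in% c("cnn_aug", "cnn_noaug", "gru")
  perFold <- list()
  audit <- list()
  conf <- matrix(0, nClasses, nClasses)
  for (si in seq_along(bySubj)) {
    subjTrials <- bySubj[[si]]
    if (!is.null(channels))
      subjTrials <- lapply(subjTrials, .subsetChannels, chans = channels)
    k <- nChannels(subjTrials[[1]])
    folds <- lotoFolds(subjTrials)
    for (fi in seq_along(folds)) {
      fold <- folds[[fi]]
      std <- fitStandardizer(fold$train)
      if (deep) {
        arr <- .evalArrangement(model, k)
        w <- length(arr)
        trainImgs <- makeImageDataset(fold$train, arr, w, std, concatMode,
                                      nClasses)
        testImgs <- makeImageDataset(list(fold$test), arr, w, std,
                                     "paper", nClasses)
        cfg <- if (is.null(dualConfig)) dualModelConfig(model)
               else dualConfig
        cfg@architecture <- model
        cfg@inputSide <- as.integer(w)
        cfg@inputChannels <- as.integer(k)
        cfg@nClasses <- as.integer(nClasses)
        cfg@seed <- .foldSeed(seed, si, fi)
        fitted <- trainDualModel(trainImgs, cfg)
        pred <- predictDual(fitted, testImgs)
        truthL <- gestureLabels(testImgs)
        truthA <- jointAngles(testImgs)
        predL <- pred$labels
        predA <- pred$angles
        trainWindowTrials <- unique(provenance(trainImgs)$trialId)
      } else {
        feats <- do.call(rbind, lapply(fold$train, function(t)
          sensorData(applyStandardizer(t, std))))
        labs <- unlist(lapply(fold$train, gestureLabels))
        angs <- unlist(lapply(fold$train, function(t)
          jointAngles(applyStandardizer(t, std))))
        clsKind <- if (model == "svm") "svc" else "rf_cls"
        regKind <- if (model == "svm") "svr" else "rf_reg"
        cfgS <- shallowCfg
        cfgS$seed <- .foldSeed(seed, si, fi)
        cls <- fitShallow(clsKind, feats, labs, cfgS)
        reg <- fitShallow(regKind, feats, angs, cfgS)
        testStd <- applyStandardizer(fold$test, std)
        predL <- predictShallow(cls, sensorData(testStd))
        predA <- predictShallow(reg, sensorData(testStd))
        truthL <- gestureLabels(testStd)
        truthA <- jointAngles(testStd)
        trainWindowTrials <- vapply(fold$train, trialId, character(1))
      }
      acc <- accuracy(predL, truthL)
      r2 <- rSquared(truthA, predA)
      conf <- conf + confusionMatrix(predL, truthL, nClasses)
      perFold[[length(perFold) + 1L]] <- data.frame(
        subjectId = subjectId(fold$test), testTrialId = fold$testTrialId,
        accuracy = acc, r2 = r2, nTest = length(truthL),
        stringsAsFactors = FALSE)
      audit[[length(audit) + 1L]] <- list(
        subjectId = subjectId(fold$test),
        testTrialId = fold$testTrialId,
        standardizerTrials = vapply(fold$train, trialId, character(1)),
        trainWindowTrials = trainWindowTrials)
    }
  }
  perFold <- do.call(rbind, perFold)
  subjSummary <- do.call(rbind, lapply(split(perFold, perFold$subjectId),
    function(df) data.frame(subjectId = df$subjectId[1],
                            accuracy = mean(df$accuracy),
                            r2 = mean(df$r2), stringsAsFactors = FALSE)))
  rownames(subjSummary) <- NULL
  subjSummary <- subjSummary[order(subjSummary$subjectId), , drop = FALSE]
  new("ExperimentResult",
      perFold = perFold, subjectSummary = subjSummary,
      grandAccuracy = mean(subjSummary$accuracy),
      grandR2 = mean(subjSummary$r2),
      accuracySd = if (nrow(subjSummary) > 1) sd(subjSummary$accuracy) else 0,
      r2Sd = if (nrow(subjSummary) > 1) sd(subjSummary$r2) else 0,
      confusion = conf, audit = audit)
}

#' Audit an experiment for train/test leakage
#'
#' Verifies, fold by fold, that the held-out trial contributed neither to
#' the fold's standardizer fit nor to its training windows.
#'
#' @param result an [ExperimentResult-class].
#' @return data.frame with one row per fold and logical columns
#'   \code{stdClean} and \code{windowsClean}; attribute \code{"clean"} is
#'   TRUE when every fold passes.
#' @export
auditLeakage <- function(result) {
  rows <- lapply(result@audit, function(a) data.frame(
    subjectId = a$subjectId, testTrialId = a$testTrialId,
    stdClean = !(a$testTrialId %in% a$standardizerTrials),
    windowsClean = !(a$testTrialId %in% a$trainWindowTrials),
    stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  attr(out, "clean") <- all(out$stdClean & out$windowsClean)
  out
}

#' Sensor-count ablation
#'
#' For each k in \code{kRange}, restricts the dataset to the top-k channels
#' of the ranking, rebuilds an arrangement for k channels (pair-complete;
#' the published fixture only at k = 10) and reruns the leave-one-trial-out
#' experiment.
#'
#' @param dataset an [FmgDataset-class].
#' @param ranking an [ImportanceRanking-class] covering all channels (or a
#'   plain permutation).
#' @param kRange sensor counts to evaluate.
#' @param model model name as in [runExperiment()].
#' @param ... passed to [runExperiment()].
#' @return data.frame with columns k, accuracy, r2, and the per-k channel
#'   subsets as attribute \code{"channels"}.
#' @export
sensorAblation <- function(dataset, ranking, kRange = NULL,
                           model = "cnn_aug", ...) {
  r <- if (is(ranking, "ImportanceRanking")) channelRanking(ranking)
       else as.integer(ranking)
  if (is.null(kRange)) kRange <- seq_along(r)
  chans <- lapply(kRange, function(k) selectTopK(r, k))
  rows <- lapply(seq_along(kRange), function(i) {
    res <- runExperiment(dataset, model = model, channels = chans[[i]], ...)
    data.frame(k = kRange[i], accuracy = res@grandAccuracy,
               r2 = res@grandR2)
  })
  out <- do.call(rbind, rows)
  attr(out, "channels") <- chans
  out
}
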