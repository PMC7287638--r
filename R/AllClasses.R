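#' Simulator configuration
#'
#' Parameters of the synthetic wristband-signal generator. Defaults follow
#' the recording protocol the models assume: 10 subjects, 10 trials each,
#' five single-finger segments per trial (thumb, index, middle, ring, pinky
#' in that order), 40 Hz sampling, 5 s per finger segment so that each trial
#' holds 5 x 5 x 40 = 1000 samples, thumb amplitude 55 degrees and 90
#' degrees for the other four fingers, self-selected flexion frequency drawn
#' from 0.4–0.6 Hz.
#'
#' Pressures are expressed in normalised full-scale units (a fully flexed
#' primary channel deflects by about \code{couplingStrength}). \code{noiseSd}
#' is the per-sample Gaussian sensor noise, \code{driftSd} the per-step
#' standard deviation of a random-walk baseline drift, and \code{crosstalk}
#' the relative strength of off-finger coupling.
#'
#' @slot nSubjects number of subjects.
#' @slot nTrialsPerSubject trials recorded per subject.
#' @slot secondsPerFinger duration of each single-finger segment (s).
#' @slot sampleRate sampling frequency (Hz); \code{secondsPerFinger *
#'   sampleRate} must be an integer.
#' @slot nChannels number of pressure channels.
#' @slot amplitudePerFinger maximum MCP angle per finger class (degrees),
#'   ordered thumb to pinky.
#' @slot flexionFreqRange interval (Hz) the per-segment flexion frequency is
#'   drawn from.
#' @slot couplingStrength overall gain of the angle-to-pressure coupling.
#' @slot crosstalk fraction in [0, 1): strength of non-primary coupling.
#' @slot noiseSd Gaussian sensor noise standard deviation (pressure units).
#' @slot driftSd random-walk drift step standard deviation (pressure units).
#' @slot attenuateAmplitude draw a per-subject amplitude attenuation factor
#'   in [0.85, 1] (some subjects cannot reach the nominal maximum angle).
#' @slot seed root seed; all randomness derives from it.
#' @seealso [simConfig()], [simulateTrial()], [simulateDataset()]
#' @export
setClass("SimConfig", representation(
  nSubjects = "integer",
  nTrialsPerSubject = "integer",
  secondsPerFinger = "numeric",
  sampleRate = "numeric",
  nChannels = "integer",
  amplitudePerFinger = "numeric",
  flexionFreqRange = "numeric",
  couplingStrength = "numeric",
  crosstalk = "numeric",
  noiseSd = "numeric",
  driftSd = "numeric",
  attenuateAmplitude = "logical",
  seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nSubjects < 1L) msg <- c(msg, "nSubjects must be >= 1")
  if (object@nTrialsPerSubject < 1L) msg <- c(msg, "nTrialsPerSubject must be >= 1")
  if (object@secondsPerFinger <= 0) msg <- c(msg, "secondsPerFinger must be > 0")
  if (object@sampleRate <= 0) msg <- c(msg, "sampleRate must be > 0")
  spf <- object@secondsPerFinger * object@sampleRate
  if (abs(spf - round(spf)) > 1e-8)
    msg <- c(msg, "secondsPerFinger * sampleRate must be an integer")
  if (object@nChannels < 2L) msg <- c(msg, "nChannels must be >= 2")
  if (length(object@amplitudePerFinger) != 5L)
    msg <- c(msg, "amplitudePerFinger must have length 5")
  if (any(object@amplitudePerFinger <= 0))
    msg <- c(msg, "amplitudePerFinger must be positive")
  if (length(object@flexionFreqRange) != 2L ||
      any(object@flexionFreqRange <= 0) ||
      diff(object@flexionFreqRange) < 0)
    msg <- c(msg, "flexionFreqRange must be a positive non-decreasing pair")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@driftSd < 0) msg <- c(msg, "driftSd must be >= 0")
  if (object@crosstalk < 0 || object@crosstalk >= 1)
    msg <- c(msg, "crosstalk must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' One recorded (or simulated) wristband trial
#'
#' A trial is a T x N matrix of channel pressures with, for every sample, the
#' active finger class (0 = thumb ... 4 = pinky) and the ground-truth MCP
#' joint angle in degrees. Labels are piecewise constant over five contiguous
#' equal-length segments in thumb-to-pinky order.
#'
#' @slot subjectId subject identifier.
#' @slot trialId trial identifier.
#' @slot pressures numeric matrix, samples x channels.
#' @slot labels integer vector of finger classes, one per sample.
#' @slot angles numeric vector of MCP angles (degrees), one per sample.
#' @slot sampleRate sampling frequency (Hz).
#' @seealso [simulateTrial()], [readTrialCsv()]
#' @export
setClass("FmgTrial", representation(
  subjectId = "character",
  trialId = "character",
  pressures = "matrix",
  labels = "integer",
  angles = "numeric",
  sampleRate = "numeric"
))

setValidity("FmgTrial", function(object) {
  msg <- character()
  n <- nrow(object@pressures)
  if (length(object@labels) != n)
    msg <- c(msg, "labels length must equal nrow(pressures)")
  if (length(object@angles) != n)
    msg <- c(msg, "angles length must equal nrow(pressures)")
  if (length(object@labels) && (min(object@labels) < 0L))
    msg <- c(msg, "labels must be non-negative class codes")
  if (any(!is.finite(object@pressures)))
    msg <- c(msg, "pressures must be finite")
  if (length(msg)) msg else TRUE
})

#' A collection of trials
#'
#' Ordered list of [FmgTrial-class] objects, usually one full simulated or
#' recorded cohort, with the generating configuration attached when known.
#'
#' @slot trials list of [FmgTrial-class].
#' @slot simConfig the [SimConfig-class] used to generate the data, or NULL.
#' @seealso [simulateDataset()]
#' @export
setClass("FmgDataset", representation(
  trials = "list",
  simConfig = "ANY"
))

setValidity("FmgDataset", function(object) {
  ok <- vapply(object@trials, function(x) is(x, "FmgTrial"), logical(1))
  if (!all(ok)) "all elements of trials must be FmgTrial objects" else TRUE
})

#' Channel arrangement for movement-image expansion
#'
#' An ordered sequence of 1-based channel indices defining the columns of the
#' expanded signal array: column j of the expanded array is a copy of source
#' channel \code{channels[j]}. Repeating channels makes channel pairs that
#' are far apart in the raw column order spatially adjacent, so a 2-D
#' convolution can see their interaction.
#'
#' @slot channels integer vector of 1-based channel indices, length M.
#' @slot nChannels N, the number of distinct source channels.
#' @slot mode construction mode, \code{"paper_fixture"}, \code{"pair_complete"}
#'   or \code{"identity"}.
#' @seealso [buildArrangement()], [expandSignals()]
#' @export
setClass("ChannelArrangement", representation(
  channels = "integer",
  nChannels = "integer",
  mode = "character"
))

setValidity("ChannelArrangement", function(object) {
  msg <- character()
  ch <- object@channels
  n <- object@nChannels
  if (any(ch < 1L) || any(ch > n))
    msg <- c(msg, "channel indices must lie in 1..nChannels")
  if (!all(seq_len(n) %in% ch))
    msg <- c(msg, "every channel 1..nChannels must appear at least once")
  if (length(msg)) msg else TRUE
})

#' Standardization parameters
#'
#' Per-channel pressure means/standard deviations and the angle mean/standard
#' deviation, fitted on a training split and applied unchanged to the test
#' split. Zero-variance channels are guarded: their sd is replaced by 1 (with
#' a warning at fit time) so standardization maps them to all zeros.
#'
#' @slot channelMean,channelSd per-channel statistics (pressure units).
#' @slot angleMean,angleSd angle statistics (degrees).
#' @slot sdConvention \code{"population"} (divide by n) or \code{"sample"}
#'   (divide by n - 1).
#' @seealso [fitStandardizer()], [applyStandardizer()]
#' @export
setClass("StandardizationParams", representation(
  channelMean = "numeric",
  channelSd = "numeric",
  angleMean = "numeric",
  angleSd = "numeric",
  sdConvention = "character"
))

setValidity("StandardizationParams", function(object) {
  msg <- character()
  if (length(object@channelMean) != length(object@channelSd))
    msg <- c(msg, "channelMean and channelSd lengths differ")
  if (any(object@channelSd <= 0) || object@angleSd <= 0)
    msg <- c(msg, "standard deviations must be > 0 (guard replaces zeros by 1)")
  if (length(msg)) msg else TRUE
})

#' A set of movement images with targets and provenance
#'
#' The model's training currency: standardized windowLen x M images cut from
#' the channel-expanded signal, each carrying one gesture label (the modal
#' class over the window), one angle target (the angle at the window's last
#' time step, standardized), and provenance (subject, trial, 0-based start
#' offset of the window).
#'
#' @slot images numeric array, windowLen x M x nImages.
#' @slot labels integer vector of per-image gesture classes.
#' @slot angles numeric vector of per-image (standardized) angle targets.
#' @slot provenance data.frame with columns subjectId, trialId, start.
#' @slot arrangement the [ChannelArrangement-class] used.
#' @slot windowLen window length (rows of each image).
#' @slot standardization the fitted [StandardizationParams-class], or NULL if
#'   the images were built from pre-standardized data.
#' @seealso [makeImageDataset()]
#' @export
setClass("MovementImageSet", representation(
  images = "array",
  labels = "integer",
  angles = "numeric",
  provenance = "data.frame",
  arrangement = "ANY",
  windowLen = "integer",
  standardization = "ANY"
))

setValidity("MovementImageSet", function(object) {
  msg <- character()
  d <- dim(object@images)
  if (length(d) != 3L) msg <- c(msg, "images must be a 3-D array")
  else {
    if (d[1] != object@windowLen)
      msg <- c(msg, "dim(images)[1] must equal windowLen")
    if (d[3] != length(object@labels) || d[3] != length(object@angles) ||
        d[3] != nrow(object@provenance))
      msg <- c(msg, "labels, angles and provenance must match image count")
  }
  if (any(!is.finite(object@images))) msg <- c(msg, "images must be finite")
  if (length(msg)) msg else TRUE
})

#' Dual-output model configuration
#'
#' Architecture and training hyperparameters of the dual-output models. The
#' defaults are the working configuration of the augmented CNN: 32 3x3
#' convolution kernels twice, 2x2 max-pooling, a 32-unit dense layer, a
#' 5-way softmax head and a 1-unit linear head, RMSprop, batch size 32, 10
#' epochs, and a 4:1 regression-to-classification loss-weight ratio.
#'
#' @slot architecture one of \code{"cnn_aug"}, \code{"cnn_noaug"},
#'   \code{"gru"}.
#' @slot inputSide image side length (42 for the augmented CNN, 10 without
#'   augmentation); for the GRU the sequence length (time steps).
#' @slot inputChannels number of signal channels seen by the GRU per step
#'   (and image width for CNNs; equals inputSide for square images).
#' @slot convFilters,kernelSize,poolSize,denseUnits CNN trunk sizes.
#' @slot nClasses K, number of gesture classes.
#' @slot wC,wR classification / regression loss weights (default 1 and 4).
#' @slot optimizer optimizer name (only \code{"rmsprop"} implemented).
#' @slot learningRate,rho,epsilon RMSprop hyperparameters.
#' @slot batchSize,epochs training loop sizes.
#' @slot gruUnits,gruDropout,gruRecurrentDropout GRU baseline sizes.
#' @slot seed seed covering weight initialisation, shuffling and dropout.
#' @seealso [dualModelConfig()], [buildDualModel()]
#' @export
setClass("DualModelConfig", representation(
  architecture = "character",
  inputSide = "integer",
  inputChannels = "integer",
  convFilters = "integer",
  kernelSize = "integer",
  poolSize = "integer",
  denseUnits = "integer",
  nClasses = "integer",
  wC = "numeric",
  wR = "numeric",
  optimizer = "character",
  learningRate = "numeric",
  rho = "numeric",
  epsilon = "numeric",
  batchSize = "integer",
  epochs = "integer",
  gruUnits = "integer",
  gruDropout = "numeric",
  gruRecurrentDropout = "numeric",
  seed = "integer"
))

setValidity("DualModelConfig", function(object) {
  msg <- character()
  if (!object@architecture %in% c("cnn_aug", "cnn_noaug", "gru"))
    msg <- c(msg, "architecture must be cnn_aug, cnn_noaug or gru")
  if (object@wC <= 0) msg <- c(msg, "wC must be > 0")
  if (object@wR < 0) msg <- c(msg, "wR must be >= 0 (0 only for diagnostics)")
  if (object@nClasses < 2L) msg <- c(msg, "nClasses must be >= 2")
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (object@optimizer != "rmsprop") msg <- c(msg, "only rmsprop is implemented")
  if (object@gruDropout < 0 || object@gruDropout >= 1 ||
      object@gruRecurrentDropout < 0 || object@gruRecurrentDropout >= 1)
    msg <- c(msg, "dropout rates must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' A trained dual-output model
#'
#' Opaque fitted parameters plus the per-epoch training history (mean
#' per-batch total, cross-entropy and mean-squared-error losses). Use
#' \code{predict()} to obtain class probabilities, hard labels and angle
#' predictions; see [predictDual()].
#'
#' @slot config the [DualModelConfig-class] the model was built from.
#' @slot params named list of weight arrays.
#' @slot shapes named list of derived layer shapes (e.g. flatten size).
#' @slot history data.frame with columns epoch, total, ce, mse.
#' @export
setClass("DualOutputModel", representation(
  config = "ANY",
  params = "list",
  shapes = "list",
  history = "data.frame"
))

#' Per-channel importance ranking
#'
#' Impurity importances from a random-forest classifier (alphaC) and
#' regressor (alphaR), each normalised to sum to one, their elementwise mean
#' (alpha), and the channel permutation sorted by descending alpha.
#'
#' @slot alphaC,alphaR,alpha per-channel importances.
#' @slot ranking integer permutation of 1..N, most important first.
#' @seealso [computeImportance()], [selectTopK()]
#' @export
setClass("ImportanceRanking", representation(
  alphaC = "numeric",
  alphaR = "numeric",
  alpha = "numeric",
  ranking = "integer"
))

setValidity("ImportanceRanking", function(object) {
  n <- length(object@alpha)
  msg <- character()
  if (length(object@alphaC) != n || length(object@alphaR) != n)
    msg <- c(msg, "alphaC, alphaR, alpha lengths differ")
  if (any(object@alphaC < 0) || any(object@alphaR < 0))
    msg <- c(msg, "importances must be non-negative")
  if (!identical(sort(object@ranking), seq_len(n)))
    msg <- c(msg, "ranking must be a permutation of 1..N")
  if (length(msg)) msg else TRUE
})

#' Leave-one-trial-out experiment result
#'
#' Per-fold metrics, per-subject summaries and the pooled grand means of a
#' leave-one-trial-out cross-validation run.
#'
#' @slot perFold data.frame: subjectId, testTrialId, accuracy, r2, nTest.
#' @slot subjectSummary data.frame: subjectId, accuracy, r2 (fold means).
#' @slot grandAccuracy,grandR2 unweighted means over subjects.
#' @slot accuracySd,r2Sd across-subject standard deviations.
#' @slot confusion K x K count matrix pooled over all folds (rows = truth).
#' @slot audit list of per-fold provenance: trials used to fit the
#'   standardizer and to build training windows, for leakage audits.
#' @seealso [runExperiment()]
#' @export
setClass("ExperimentResult", representation(
  perFold = "data.frame",
  subjectSummary = "data.frame",
  grandAccuracy = "numeric",
  grandR2 = "numeric",
  accuracySd = "numeric",
  r2Sd = "numeric",
  confusion = "matrix",
  audit = "list"
))

#' Paired model comparison result
#'
#' Exact Wilcoxon signed-rank comparison of two models' per-subject scores.
#'
#' @slot modelA,modelB model names.
#' @slot valuesA,valuesB paired per-subject values.
#' @slot statistic signed-rank statistic W (sum of ranks of positive
#'   differences, A minus B).
#' @slot pValue exact two-sided p-value.
#' @slot significant TRUE when pValue < 0.05.
#' @slot nZeroDropped number of zero differences dropped before ranking.
#' @seealso [pairedSignedRankTest()]
#' @export
setClass("ComparisonResult", representation(
  modelA = "character",
  modelB = "character",
  valuesA = "numeric",
  valuesB = "numeric",
  statistic = "numeric",
  pValue = "numeric",
  significant = "logical",
  nZeroDropped = "integer"
))
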