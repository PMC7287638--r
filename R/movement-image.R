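#' Slice a signal array into sliding windows
#'
#' Unit-step sliding windows over the time axis. A length-Ls series with
#' window length w yields exactly \code{Ls - w} windows with 0-based start
#' offsets \code{1..Ls-w}: the first possible window (offset 0) is dropped
#' so that the final window ends exactly at the last sample, matching the
#' augmentation's published dimension arithmetic (e.g. 1000 samples ->
#' 958 windows of length 42).
#'
#' @param expanded Ls x M signal matrix (already channel-expanded).
#' @param windowLen w, rows per window.
#' @return list with \code{windows}, a w x M x (Ls - w) array, and
#'   \code{starts}, the 0-based start offsets.
#' @examples
#' sw <- sliceWindows(matrix(1:20, ncol = 2), 3)
#' dim(sw$windows)  # 3 2 7
#' @export
sliceWindows <- function(expanded, windowLen) {
  ls <- nrow(expanded)
  m <- ncol(expanded)
  w <- as.integer(windowLen)
  if (ls <= w)
    stop("insufficient length: need more than ", w, " rows, got ", ls)
  starts <- seq_len(ls - w)            # 0-based offsets 1..Ls-w
  rows <- outer(seq_len(w), starts, "+")  # w x n matrix of source rows
  gathered <- expanded[as.vector(rows), , drop = FALSE]   # (w*n) x M
  windows <- aperm(array(gathered, c(w, length(starts), m)), c(1L, 3L, 2L))
  list(windows = windows, starts = starts)
}

#' Assign the label and angle target of one window
#'
#' The window's gesture label is the modal class of its per-sample labels;
#' the angle target is the angle at the window's last time step. Ties in
#' the mode are broken in favour of the tied class whose last occurrence in
#' the window is latest (consistent with the last-time-step convention of
#' the angle target, and deterministic).
#'
#' @param windowLabels integer vector of per-sample classes.
#' @param windowAngles numeric vector of per-sample angles.
#' @return list with \code{label} and \code{angleTarget}.
#' @export
assignTargets <- function(windowLabels, windowAngles) {
  w <- length(windowLabels)
  if (w < 1L || length(windowAngles) != w)
    stop("invalid input: non-empty, equal-length labels and angles required")
  counts <- table(windowLabels)
  top <- names(counts)[counts == max(counts)]
  if (length(top) > 1L) {
    lastOcc <- vapply(top, function(cl)
      max(which(windowLabels == as.integer(cl))), integer(1))
    top <- top[which.max(lastOcc)]
  }
  list(label = as.integer(top), angleTarget = windowAngles[w])
}

# vectorised modal labels for all windows of one contiguous label vector;
# same tie-break as assignTargets.
.windowModes <- function(labels, starts, w, nClasses) {
  n <- length(starts)
  out <- integer(n)
  for (k in seq_len(n)) {
    seg <- labels[(starts[k] + 1L):(starts[k] + w)]
    cnt <- tabulate(seg + 1L, nbins = nClasses)
    mx <- which(cnt == max(cnt)) - 1L
    if (length(mx) == 1L) out[k] <- mx
    else {
      lastOcc <- vapply(mx, function(cl) max(which(seg == cl)), integer(1))
      out[k] <- mx[which.max(lastOcc)]
    }
  }
  out
}

#' Fit standardization parameters on training trials
#'
#' Per-channel pressure means and standard deviations plus the angle mean
#' and standard deviation, computed over all samples of the supplied
#' training trials. Fit on the training split of a fold only and apply
#' unchanged to its test split. The default convention is the population
#' standard deviation (divide by n). Zero-variance channels are guarded:
#' their sd is replaced by 1 (warning), so they standardize to all zeros.
#'
#' @param trainTrials list of [FmgTrial-class] (or an [FmgDataset-class]).
#' @param sdConvention \code{"population"} or \code{"sample"}.
#' @return a [StandardizationParams-class].
#' @export
fitStandardizer <- function(trainTrials,
                            sdConvention = c("population", "sample")) {
  sdConvention <- match.arg(sdConvention)
  if (is(trainTrials, "FmgDataset")) trainTrials <- trials(trainTrials)
  if (is(trainTrials, "FmgTrial")) trainTrials <- list(trainTrials)
  if (!length(trainTrials)) stop("invalid input: no training trials")
  press <- do.call(rbind, lapply(trainTrials, sensorData))
  ang <- unlist(lapply(trainTrials, jointAngles))
  n <- nrow(press)
  mu <- colMeans(press)
  ctr <- sweep(press, 2, mu)
  ss <- colSums(ctr^2)
  denom <- if (sdConvention == "population") n else n - 1L
  sds <- sqrt(ss / denom)
  aMu <- mean(ang)
  aSd <- sqrt(sum((ang - aMu)^2) / denom)
  zv <- sds <= .Machine$double.eps * 1e3
  if (any(zv)) {
    warning("zero-variance channel(s) ", paste(which(zv), collapse = ", "),
            ": sd guarded to 1")
    sds[zv] <- 1
  }
  if (aSd <= .Machine$double.eps * 1e3) {
    warning("zero-variance angles: sd guarded to 1")
    aSd <- 1
  }
  new("StandardizationParams", channelMean = unname(mu),
      channelSd = unname(sds), angleMean = aMu, angleSd = aSd,
      sdConvention = sdConvention)
}

#' Apply (or invert) standardization
#'
#' \code{applyStandardizer} standardizes a trial's pressures and angles with
#' previously fitted parameters; \code{standardizeAngles} and
#' \code{unstandardizeAngles} convert angle vectors between the degree and
#' standardized scales.
#'
#' @param trial an [FmgTrial-class].
#' @param params a [StandardizationParams-class].
#' @return a standardized [FmgTrial-class].
#' @export
applyStandardizer <- function(trial, params) {
  if (ncol(sensorData(trial)) != length(params@channelMean))
    stop("shape error: channel count mismatch")
  p <- sweep(sweep(sensorData(trial), 2, params@channelMean), 2,
             params@channelSd, "/")
  a <- (jointAngles(trial) - params@angleMean) / params@angleSd
  initialize(trial, pressures = p, angles = a)
}

#' @rdname applyStandardizer
#' @param angles numeric vector of angles (degrees or standardized).
#' @export
standardizeAngles <- function(angles, params)
  (angles - params@angleMean) / params@angleSd

#' @rdname applyStandardizer
#' @export
unstandardizeAngles <- function(angles, params)
  angles * params@angleSd + params@angleMean

#' Build a movement-image dataset from trials
#'
#' The full augmentation pipeline: standardize each trial with the supplied
#' (training-fitted) parameters, expand channels along the arrangement,
#' window the expanded array, and assign each image its modal-class label
#' and last-step (standardized) angle target.
#'
#' Two concatenation modes: \code{"paper"} concatenates a split's trials
#' along time before windowing (so 9 x 1000-sample training trials give
#' 9000 - 42 images, a few of which straddle trial boundaries);
#' \code{"per_trial"} windows each trial separately (9 x 958 images, no
#' cross-trial windows).
#'
#' @param trialList list of [FmgTrial-class] (or an [FmgDataset-class]);
#'   all trials must share the channel count.
#' @param arrangement a [ChannelArrangement-class].
#' @param windowLen image window length; the published configuration uses
#'   the arrangement length M, giving square M x M images.
#' @param standardizer a fitted [StandardizationParams-class], or NULL to
#'   fit on \code{trialList} itself (only appropriate when the list is a
#'   training split).
#' @param concatMode \code{"paper"} or \code{"per_trial"}.
#' @param nClasses number of gesture classes.
#' @return a [MovementImageSet-class]. Provenance records each image's
#'   subject, the trial containing its last sample (the sample its angle
#'   target comes from), and its 0-based start offset within the
#'   windowed block.
#' @examples
#' cfg <- simConfig(nSubjects = 1, nTrialsPerSubject = 1, secondsPerFinger = 2)
#' tr <- simulateTrial(cfg, 1, 1)
#' arr <- buildArrangement(10, "paper_fixture")
#' imgs <- makeImageDataset(list(tr), arr)
#' length(imgs)  # 400 - 42 = 358
#' @export
makeImageDataset <- function(trialList, arrangement, windowLen = NULL,
                             standardizer = NULL,
                             concatMode = c("paper", "per_trial"),
                             nClasses = 5L) {
  concatMode <- match.arg(concatMode)
  if (is(trialList, "FmgDataset")) trialList <- trials(trialList)
  if (is(trialList, "FmgTrial")) trialList <- list(trialList)
  if (!length(trialList)) stop("invalid input: no trials")
  ncs <- vapply(trialList, nChannels, integer(1))
  if (length(unique(ncs)) != 1L)
    stop("shape error: trials have mixed channel counts")
  if (ncs[1] != nChannels(arrangement))
    stop("shape error: arrangement expects ", nChannels(arrangement),
         " channels, trials have ", ncs[1])
  if (is.null(windowLen)) windowLen <- length(arrangement)
  w <- as.integer(windowLen)
  if (is.null(standardizer)) standardizer <- fitStandardizer(trialList)
  std <- lapply(trialList, applyStandardizer, params = standardizer)

  blocks <- if (concatMode == "paper") list(std) else
    lapply(std, list)
  imgsL <- list(); labsL <- list(); angsL <- list(); provL <- list()
  for (b in blocks) {
    press <- do.call(rbind, lapply(b, sensorData))
    labs <- unlist(lapply(b, gestureLabels))
    angs <- unlist(lapply(b, jointAngles))
    subjRow <- unlist(lapply(b, function(t)
      rep(subjectId(t), nSamples(t))))
    trialRow <- unlist(lapply(b, function(t)
      rep(trialId(t), nSamples(t))))
    expanded <- expandSignals(press, arrangement)
    sw <- sliceWindows(expanded, w)
    lastRows <- sw$starts + w
    labsW <- .windowModes(labs, sw$starts, w, nClasses)
    imgsL[[length(imgsL) + 1L]] <- sw$windows
    labsL[[length(labsL) + 1L]] <- labsW
    angsL[[length(angsL) + 1L]] <- angs[lastRows]
    provL[[length(provL) + 1L]] <- data.frame(
      subjectId = subjRow[lastRows], trialId = trialRow[lastRows],
      start = sw$starts, stringsAsFactors = FALSE)
  }
  m <- length(arrangement)
  nTot <- sum(vapply(imgsL, function(a) dim(a)[3], integer(1)))
  images <- array(0, c(w, m, nTot))
  at <- 0L
  for (a in imgsL) {
    k <- dim(a)[3]
    images[, , at + seq_len(k)] <- a
    at <- at + k
  }
  new("MovementImageSet",
      images = images,
      labels = as.integer(unlist(labsL)),
      angles = as.numeric(unlist(angsL)),
      provenance = do.call(rbind, provL),
      arrangement = arrangement,
      windowLen = w,
      standardization = standardizer)
}

#' Serialize / load a movement-image dataset
#'
#' Image sets are stored with R's native serialization (\code{saveRDS},
#' version 3, xz-free default compression); the object round-trips exactly.
#'
#' @param imageSet a [MovementImageSet-class].
#' @param path file path.
#' @return \code{readImageSet} returns the [MovementImageSet-class].
#' @export
writeImageSet <- function(imageSet, path) {
  saveRDS(imageSet, path)
  invisible(path)
}

#' @rdname writeImageSet
#' @export
readImageSet <- function(path) {
  obj <- readRDS(path)
  if (!is(obj, "MovementImageSet")) stop("not a MovementImageSet file")
  obj
}
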