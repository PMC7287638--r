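#' @name fmgdual-accessors
#' @title Accessors for fmgdual classes
#'
#' @description Slot accessors. \code{sensorData()} returns the T x N
#' pressure matrix of a trial; \code{gestureLabels()} the per-sample (or
#' per-image) finger classes; \code{jointAngles()} the angles / angle
#' targets; \code{images()} the image array of a [MovementImageSet-class];
#' \code{channelRanking()} the descending-importance channel permutation.
#'
#' @param x an fmgdual object.
#' @return the corresponding slot value.
NULL

#' @rdname fmgdual-accessors
#' @export
setGeneric("sensorData", function(x) standardGeneric("sensorData"))
#' @rdname fmgdual-accessors
#' @export
setGeneric("gestureLabels", function(x) standardGeneric("gestureLabels"))
#' @rdname fmgdual-accessors
#' @export
setGeneric("jointAngles", function(x) standardGeneric("jointAngles"))
#' @rdname fmgdual-accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))
#' @rdname fmgdual-accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname fmgdual-accessors
#' @export
setGeneric("trialId", function(x) standardGeneric("trialId"))
#' @rdname fmgdual-accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname fmgdual-accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname fmgdual-accessors
#' @export
setGeneric("trials", function(x) standardGeneric("trials"))
#' @rdname fmgdual-accessors
#' @export
setGeneric("images", function(x) standardGeneric("images"))
#' @rdname fmgdual-accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname fmgdual-accessors
#' @export
setGeneric("arrangement", function(x) standardGeneric("arrangement"))
#' @rdname fmgdual-accessors
#' @export
setGeneric("windowLen", function(x) standardGeneric("windowLen"))
#' @rdname fmgdual-accessors
#' @export
setGeneric("channelRanking", function(x) standardGeneric("channelRanking"))
#' @rdname fmgdual-accessors
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))

# ---- FmgTrial ----

#' @rdname fmgdual-accessors
setMethod("sensorData", "FmgTrial", function(x) x@pressures)
#' @rdname fmgdual-accessors
setMethod("gestureLabels", "FmgTrial", function(x) x@labels)
#' @rdname fmgdual-accessors
setMethod("jointAngles", "FmgTrial", function(x) x@angles)
#' @rdname fmgdual-accessors
setMethod("sampleRate", "FmgTrial", function(x) x@sampleRate)
#' @rdname fmgdual-accessors
setMethod("subjectId", "FmgTrial", function(x) x@subjectId)
#' @rdname fmgdual-accessors
setMethod("trialId", "FmgTrial", function(x) x@trialId)
#' @rdname fmgdual-accessors
setMethod("nChannels", "FmgTrial", function(x) ncol(x@pressures))
#' @rdname fmgdual-accessors
setMethod("nSamples", "FmgTrial", function(x) nrow(x@pressures))

setMethod("show", "FmgTrial", function(object) {
  cat(sprintf(
    "FmgTrial subject=%s trial=%s: %d samples x %d channels @ %g Hz\n",
    object@subjectId, object@trialId, nrow(object@pressures),
    ncol(object@pressures), object@sampleRate))
  cat(sprintf("  classes: %s; angle range [%.1f, %.1f] deg\n",
              paste(sort(unique(object@labels)), collapse = " "),
              min(object@angles), max(object@angles)))
})

# ---- FmgDataset ----

#' @rdname fmgdual-accessors
setMethod("trials", "FmgDataset", function(x) x@trials)

#' @describeIn fmgdual-accessors number of trials in the dataset.
#' @export
setMethod("length", "FmgDataset", function(x) length(x@trials))

#' @describeIn fmgdual-accessors extract one trial.
#' @param i trial index.
#' @export
setMethod("[[", "FmgDataset", function(x, i) x@trials[[i]])

setMethod("show", "FmgDataset", function(object) {
  subj <- unique(vapply(object@trials, function(t) t@subjectId, character(1)))
  cat(sprintf("FmgDataset: %d trials, %d subjects\n",
              length(object@trials), length(subj)))
})

# ---- ChannelArrangement ----

#' @rdname fmgdual-accessors
setMethod("nChannels", "ChannelArrangement", function(x) x@nChannels)

#' @describeIn fmgdual-accessors M, the number of expanded columns.
#' @export
setMethod("length", "ChannelArrangement", function(x) length(x@channels))

#' @rdname fmgdual-accessors
#' @export
setGeneric("channels", function(x) standardGeneric("channels"))
#' @rdname fmgdual-accessors
setMethod("channels", "ChannelArrangement", function(x) x@channels)

setMethod("show", "ChannelArrangement", function(object) {
  cat(sprintf("ChannelArrangement (%s): N=%d -> M=%d\n  [%s]\n",
              object@mode, object@nChannels, length(object@channels),
              paste(object@channels, collapse = ", ")))
})

# ---- MovementImageSet ----

#' @rdname fmgdual-accessors
setMethod("images", "MovementImageSet", function(x) x@images)
#' @rdname fmgdual-accessors
setMethod("gestureLabels", "MovementImageSet", function(x) x@labels)
#' @rdname fmgdual-accessors
setMethod("jointAngles", "MovementImageSet", function(x) x@angles)
#' @rdname fmgdual-accessors
setMethod("provenance", "MovementImageSet", function(x) x@provenance)
#' @rdname fmgdual-accessors
setMethod("arrangement", "MovementImageSet", function(x) x@arrangement)
#' @rdname fmgdual-accessors
setMethod("windowLen", "MovementImageSet", function(x) x@windowLen)

#' @describeIn fmgdual-accessors number of images.
#' @export
setMethod("length", "MovementImageSet", function(x) dim(x@images)[3])

#' @describeIn fmgdual-accessors subset an image set by image index.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "MovementImageSet", function(x, i, j, ..., drop = FALSE) {
  new("MovementImageSet",
      images = x@images[, , i, drop = FALSE],
      labels = x@labels[i],
      angles = x@angles[i],
      provenance = x@provenance[i, , drop = FALSE],
      arrangement = x@arrangement,
      windowLen = x@windowLen,
      standardization = x@standardization)
})

setMethod("show", "MovementImageSet", function(object) {
  d <- dim(object@images)
  cat(sprintf("MovementImageSet: %d images of %d x %d\n", d[3], d[1], d[2]))
  tab <- table(object@labels)
  cat("  labels:", paste(sprintf("%s:%d", names(tab), tab), collapse = " "), "\n")
})

# ---- DualOutputModel ----

#' @rdname fmgdual-accessors
setMethod("trainingHistory", "DualOutputModel", function(x) x@history)

setMethod("show", "DualOutputModel", function(object) {
  cfg <- object@config
  cat(sprintf("DualOutputModel (%s): %d classes + 1 angle head\n",
              cfg@architecture, cfg@nClasses))
  if (nrow(object@history)) {
    h <- object@history[nrow(object@history), ]
    cat(sprintf("  trained %d epochs; final loss total=%.4f ce=%.4f mse=%.4f\n",
                nrow(object@history), h$total, h$ce, h$mse))
  } else cat("  untrained\n")
})

# ---- ImportanceRanking ----

#' @rdname fmgdual-accessors
setMethod("channelRanking", "ImportanceRanking", function(x) x@ranking)

setMethod("show", "ImportanceRanking", function(object) {
  cat("ImportanceRanking:", paste(object@ranking, collapse = " "), "\n")
  cat("  alpha:", paste(sprintf("%.3f", object@alpha), collapse = " "), "\n")
})

# ---- ExperimentResult ----

setMethod("show", "ExperimentResult", function(object) {
  cat(sprintf(
    "ExperimentResult: %d folds, %d subjects\n  accuracy %.3f (sd %.3f), R2 %.3f (sd %.3f)\n",
    nrow(object@perFold), nrow(object@subjectSummary),
    object@grandAccuracy, object@accuracySd, object@grandR2, object@r2Sd))
})

# ---- ComparisonResult ----

setMethod("show", "ComparisonResult", function(object) {
  cat(sprintf(
    "ComparisonResult %s vs %s: W=%g, exact two-sided p=%.5g%s\n",
    object@modelA, object@modelB, object@statistic, object@pValue,
    if (object@significant) " (significant at 0.05)" else ""))
})
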