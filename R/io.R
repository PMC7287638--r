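#' Read / write trial CSV files
#'
#' The trial interchange format is a header-carrying CSV with one row per
#' sample and columns \code{s1..sN,label,angle}: N sensor pressures, the
#' 0-based finger class (0 = thumb ... 4 = pinky) and the MCP angle in
#' degrees. Round-trips are lossless to full double precision (values are
#' written with 17 significant digits).
#'
#' @param path CSV file path.
#' @param subjectIdent,trialIdent identifiers attached to the trial on read
#'   (the CSV itself carries only samples; identity lives in the manifest).
#' @param sampleRateHz sampling frequency attached on read.
#' @param nClasses label range guard (labels must lie in 0..K-1).
#' @param nChannels expected sensor column count (default 10, the wristband
#'   schema); NULL accepts any channel count (channel-subset files).
#' @return \code{readTrialCsv} returns an [FmgTrial-class].
#' @export
readTrialCsv <- function(path, subjectIdent = "S01", trialIdent = "T01",
                         sampleRateHz = 40, nClasses = 5L,
                         nChannels = 10L) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "numeric")
  nm <- names(df)
  ns <- length(nm) - 2L
  expect <- c(paste0("s", seq_len(max(ns, 1))), "label", "angle")
  if (ns < 1L || !identical(nm, expect))
    stop("parse error in ", path, ": header must be s1..sN,label,angle, got ",
         paste(nm, collapse = ","))
  if (!is.null(nChannels) && ns != nChannels)
    stop("parse error in ", path, ": expected ", nChannels,
         " sensor columns, found ", ns)
  for (j in seq_along(df)) {
    bad <- which(!is.finite(df[[j]]))
    if (length(bad))
      stop("parse error in ", path, ": non-numeric cell at row ", bad[1],
           ", column ", nm[j])
  }
  lab <- df$label
  if (any(lab != round(lab)))
    stop("parse error in ", path, ": label column must be integer-valued (row ",
         which(lab != round(lab))[1], ")")
  if (any(lab < 0 | lab >= nClasses))
    stop("parse error in ", path, ": label outside 0..", nClasses - 1L,
         " at row ", which(lab < 0 | lab >= nClasses)[1])
  press <- as.matrix(df[, seq_len(ns), drop = FALSE])
  colnames(press) <- paste0("s", seq_len(ns))
  new("FmgTrial", subjectId = subjectIdent, trialId = trialIdent,
      pressures = press, labels = as.integer(lab),
      angles = as.numeric(df$angle), sampleRate = sampleRateHz)
}

#' @rdname readTrialCsv
#' @param trial an [FmgTrial-class].
#' @export
writeTrialCsv <- function(trial, path) {
  press <- sensorData(trial)
  df <- as.data.frame(press)
  names(df) <- paste0("s", seq_len(ncol(press)))
  df$label <- gestureLabels(trial)
  df$angle <- jointAngles(trial)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con)
  cols <- lapply(df, function(x) format(x, digits = 17, trim = TRUE))
  writeLines(do.call(paste, c(cols, sep = ",")), con)
  invisible(path)
}

#' Read / write a dataset manifest
#'
#' Plain-text table (TSV) mapping trials to their CSV files, with columns
#' subjectId, trialId, path (relative to the manifest's directory), and
#' sampleRate.
#'
#' @param dataset an [FmgDataset-class].
#' @param dir output directory (created if missing); one CSV per trial is
#'   written plus \code{manifest.tsv}.
#' @return \code{writeDatasetCsv} returns the manifest path;
#'   \code{readDatasetCsv} returns an [FmgDataset-class].
#' @export
writeDatasetCsv <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(trials(dataset), function(tr) {
    fn <- sprintf("%s_%s.csv", subjectId(tr), trialId(tr))
    writeTrialCsv(tr, file.path(dir, fn))
    data.frame(subjectId = subjectId(tr), trialId = trialId(tr),
               path = fn, sampleRate = sampleRate(tr),
               stringsAsFactors = FALSE)
  })
  man <- do.call(rbind, rows)
  manPath <- file.path(dir, "manifest.tsv")
  utils::write.table(man, manPath, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(manPath)
}

#' @rdname writeDatasetCsv
#' @param manifestPath path to a manifest.tsv.
#' @export
readDatasetCsv <- function(manifestPath) {
  man <- utils::read.delim(manifestPath, stringsAsFactors = FALSE)
  need <- c("subjectId", "trialId", "path", "sampleRate")
  if (!all(need %in% names(man)))
    stop("parse error: manifest must have columns ",
         paste(need, collapse = ", "))
  base <- dirname(manifestPath)
  trialsL <- lapply(seq_len(nrow(man)), function(i)
    readTrialCsv(file.path(base, man$path[i]), man$subjectId[i],
                 man$trialId[i], man$sampleRate[i], nChannels = NULL))
  new("FmgDataset", trials = trialsL, simConfig = NULL)
}

# ---- run configuration ----

.runConfigDefaults <- function() {
  list(
    seed = 1L,
    outputDir = ".",
    verbosity = "info",
    sim = list(nSubjects = 10L, nTrialsPerSubject = 10L,
               secondsPerFinger = 5, sampleRate = 40, nChannels = 10L,
               noiseSd = 0.05, driftSd = 0.002, crosstalk = 0.15),
    augment = list(windowLen = 42L, arrangement = "paper_fixture",
                   concatMode = "paper"),
    model = list(architecture = "cnn_aug", weightRatio = "4:1",
                 batchSize = 32L, epochs = 10L, learningRate = 0.001),
    shallow = list(svcC = 5, svcGamma = 0.1, svrC = 10, svrGamma = 0.1,
                   rfClsTrees = 100L, rfRegTrees = 60L),
    evaluate = list(concatMode = "paper", nClasses = 5L))
}

#' Parse a "wR:wC" weight-ratio string
#'
#' @param ratio string like \code{"4:1"} (regression:classification).
#' @return list with \code{wR} and \code{wC}.
#' @export
parseWeightRatio <- function(ratio) {
  parts <- suppressWarnings(as.numeric(strsplit(ratio, ":", fixed = TRUE)[[1]]))
  if (length(parts) != 2L || any(!is.finite(parts)) || any(parts < 0) ||
      parts[2] <= 0)
    stop("validation error: weightRatio must look like \"4:1\"")
  list(wR = parts[1], wC = parts[2])
}

#' Load a run configuration
#'
#' Reads a YAML configuration with sections \code{sim}, \code{augment},
#' \code{model}, \code{shallow}, \code{evaluate} plus top-level
#' \code{seed}, \code{outputDir}, \code{verbosity}. Unknown keys are
#' rejected; omitted keys take the defaults of the working configuration
#' (window 42, weight ratio 4:1, batch 32, 10 epochs, SVC C=5 gamma=0.1,
#' SVR C=10 gamma=0.1, 100/60 forest trees); every defaulted key is
#' reported at load time via \code{message()}.
#'
#' @param path YAML file path; an empty or absent-section file yields all
#'   defaults.
#' @return nested named list (classed \code{fmgRunConfig}).
#' @export
loadRunConfig <- function(path) {
  defaults <- .runConfigDefaults()
  user <- if (file.exists(path)) yaml::read_yaml(path) else
    stop("config file not found: ", path)
  if (is.null(user)) user <- list()
  cfg <- defaults
  defaulted <- character()
  unknown <- character()
  for (key in names(user)) {
    if (!key %in% names(defaults)) { unknown <- c(unknown, key); next }
    if (is.list(defaults[[key]])) {
      sec <- user[[key]]
      if (!is.list(sec)) { unknown <- c(unknown, key); next }
      for (k2 in names(sec)) {
        if (!k2 %in% names(defaults[[key]]))
          unknown <- c(unknown, paste(key, k2, sep = "."))
        else cfg[[key]][[k2]] <- sec[[k2]]
      }
    } else cfg[[key]] <- user[[key]]
  }
  if (length(unknown))
    stop("schema violation: unknown config key(s): ",
         paste(unknown, collapse = ", "))
  for (key in names(defaults)) {
    if (is.list(defaults[[key]])) {
      for (k2 in names(defaults[[key]]))
        if (is.null(user[[key]][[k2]]))
          defaulted <- c(defaulted, paste(key, k2, sep = "."))
    } else if (is.null(user[[key]])) defaulted <- c(defaulted, key)
  }
  if (cfg$model$epochs < 1)
    stop("validation error: model.epochs must be >= 1")
  if (cfg$augment$windowLen < 2)
    stop("validation error: augment.windowLen must be >= 2")
  wr <- parseWeightRatio(cfg$model$weightRatio)
  cfg$model$wR <- wr$wR
  cfg$model$wC <- wr$wC
  if (length(defaulted))
    message("config defaults applied: ", paste(defaulted, collapse = ", "))
  class(cfg) <- "fmgRunConfig"
  cfg
}
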