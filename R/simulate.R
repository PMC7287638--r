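#' Build a simulator configuration
#'
#' Constructor for [SimConfig-class] with the default recording protocol:
#' 10 subjects x 10 trials, five single-finger segments of 5 s at 40 Hz
#' (1000 samples per trial, 100,000 samples in the full design), thumb
#' amplitude 55 degrees, 90 degrees for the other fingers, self-selected
#' flexion frequency in 0.4–0.6 Hz.
#'
#' @param nSubjects,nTrialsPerSubject cohort size.
#' @param secondsPerFinger,sampleRate segment duration (s) and sampling
#'   frequency (Hz); their product must be an integer.
#' @param nChannels number of wristband pressure channels.
#' @param amplitudePerFinger per-finger maximum MCP angle (degrees).
#' @param flexionFreqRange interval the per-segment flexion frequency is
#'   drawn from (Hz).
#' @param couplingStrength,crosstalk,noiseSd,driftSd signal-model knobs; see
#'   [SimConfig-class].
#' @param attenuateAmplitude per-subject amplitude attenuation in
#'   [0.85, 1] (subjects who cannot reach the nominal maximum).
#' @param seed root seed for all randomness.
#' @return a validated [SimConfig-class].
#' @examples
#' cfg <- simConfig(nSubjects = 1, nTrialsPerSubject = 1, seed = 7)
#' trial <- simulateTrial(cfg, 1, 1)
#' nSamples(trial)  # 1000
#' @export
simConfig <- function(nSubjects = 10L, nTrialsPerSubject = 10L,
                      secondsPerFinger = 5, sampleRate = 40,
                      nChannels = 10L,
                      amplitudePerFinger = c(55, 90, 90, 90, 90),
                      flexionFreqRange = c(0.4, 0.6),
                      couplingStrength = 1, crosstalk = 0.15,
                      noiseSd = 0.05, driftSd = 0.002,
                      attenuateAmplitude = TRUE, seed = 1L) {
  new("SimConfig",
      nSubjects = as.integer(nSubjects),
      nTrialsPerSubject = as.integer(nTrialsPerSubject),
      secondsPerFinger = as.numeric(secondsPerFinger),
      sampleRate = as.numeric(sampleRate),
      nChannels = as.integer(nChannels),
      amplitudePerFinger = as.numeric(amplitudePerFinger),
      flexionFreqRange = as.numeric(flexionFreqRange),
      couplingStrength = as.numeric(couplingStrength),
      crosstalk = as.numeric(crosstalk),
      noiseSd = as.numeric(noiseSd),
      driftSd = as.numeric(driftSd),
      attenuateAmplitude = isTRUE(attenuateAmplitude),
      seed = as.integer(seed))
}

# Deterministic per-(subject, trial) seed derivation from the root seed, so
# any single trial is reproducible in isolation. Kept below 2^31 - 1.
.deriveSeed <- function(rootSeed, subjectIdx, trialIdx = 0L) {
  as.integer((as.numeric(rootSeed) + 1299709 * subjectIdx +
                104729 * trialIdx) %% 2147483647)
}

#' Raised-cosine MCP-angle trajectory
#'
#' One finger's flexion/extension trajectory: theta(t) = amplitude/2 *
#' (1 - cos(2 pi freq t + phase)). The trajectory oscillates between 0
#' (fully extended) and \code{amplitude} degrees (fully flexed), hitting
#' both extremes once per period.
#'
#' @param fingerClass finger class code 0..4 (thumb..pinky); informational.
#' @param duration segment duration (s).
#' @param sampleRate sampling frequency (Hz).
#' @param amplitude maximum angle (degrees), > 0.
#' @param freq flexion frequency (Hz), > 0.
#' @param phase phase offset (radians).
#' @return numeric vector of \code{duration * sampleRate} angles (degrees).
#' @examples
#' th <- angleTrajectory(0, duration = 2, sampleRate = 40,
#'                       amplitude = 55, freq = 0.5)
#' range(th)  # 0 .. 55
#' @export
angleTrajectory <- function(fingerClass, duration, sampleRate, amplitude,
                            freq, phase = 0) {
  if (duration <= 0 || sampleRate <= 0)
    stop("invalid config: duration and sampleRate must be positive")
  if (amplitude <= 0) stop("invalid config: amplitude must be positive")
  if (freq <= 0) stop("invalid config: freq must be positive")
  n <- round(duration * sampleRate)
  t <- (seq_len(n) - 1) / sampleRate
  amplitude / 2 * (1 - cos(2 * pi * freq * t + phase))
}

# Monotone saturating normalized-angle -> pressure map on [0, 1];
# g(0) = 0, g(1) = 1. The steepness keeps the map well conditioned over
# the whole range (the slope stays bounded away from 0 at full flexion),
# so the joint angle stays recoverable from the pressures everywhere.
.saturate <- function(u) tanh(1.5 * u) / tanh(1.5)

#' Per-subject channel coupling
#'
#' Draws the subject's channels x fingers coupling matrix and per-channel
#' baseline. Each finger drives two primary channels strongly (distinct
#' pairs per finger, so class-conditional activation patterns differ) plus
#' weaker neighbouring and crosstalk couplings; a log-normal jitter models
#' inter-subject variability. Deterministic given (config seed, subject).
#'
#' @param config a [SimConfig-class].
#' @param subjectIdx subject index (1-based).
#' @return list with elements \code{coupling} (nChannels x 5),
#'   \code{baseline} (nChannels), \code{amplitudeScale} (scalar in
#'   [0.85, 1], or 1 when attenuation is off).
#' @export
subjectCoupling <- function(config, subjectIdx) {
  nc <- config@nChannels
  set.seed(.deriveSeed(config@seed, subjectIdx, 0L))
  cp <- matrix(0, nrow = nc, ncol = 5)
  for (f in 1:5) {
    p1 <- ((2 * (f - 1)) %% nc) + 1L
    p2 <- ((2 * f - 1) %% nc) + 1L
    nb <- ((2 * (f - 1) - 1) %% nc) + 1L
    cp[p1, f] <- 1.0
    cp[p2, f] <- 0.8
    cp[nb, f] <- cp[nb, f] + 0.35
    others <- setdiff(seq_len(nc), c(p1, p2, nb))
    cp[others, f] <- config@crosstalk * runif(length(others), 0.1, 0.5)
  }
  jitter <- matrix(exp(rnorm(nc * 5, 0, 0.15)), nrow = nc)
  cp <- config@couplingStrength * cp * jitter
  baseline <- runif(nc, 0.05, 0.15)
  ampScale <- if (config@attenuateAmplitude) runif(1, 0.85, 1) else 1
  # the self-selected flexion pace is a subject trait: drawn once per
  # subject, with only small per-segment variation at trial time
  pace <- runif(1, config@flexionFreqRange[1], config@flexionFreqRange[2])
  list(coupling = cp, baseline = baseline, amplitudeScale = ampScale,
       pace = pace)
}

#' Map finger angles to wristband pressures
#'
#' pressures = baseline + coupling %*% g(angle / amplitude) + random-walk
#' drift + Gaussian noise, with g a fixed monotone saturating map
#' (tanh-shaped, g(0) = 0, g(1) = 1). With \code{noiseSd = driftSd = 0}
#' the output is an exact deterministic function of the angles; the same
#' seed always reproduces the same matrix.
#'
#' @param anglesByFinger T x 5 matrix of per-finger MCP angles (degrees);
#'   inactive fingers are 0.
#' @param coupling nChannels x 5 non-negative coupling matrix.
#' @param baseline per-channel baseline pressure.
#' @param noiseSd,driftSd noise magnitudes (pressure units).
#' @param seed seed for the noise draws.
#' @param amplitudePerFinger per-finger amplitude used to normalise angles
#'   to [0, 1] before the saturating map.
#' @return T x nChannels pressure matrix.
#' @export
sensorResponse <- function(anglesByFinger, coupling, baseline,
                           noiseSd = 0, driftSd = 0, seed = 1L,
                           amplitudePerFinger = c(55, 90, 90, 90, 90)) {
  if (ncol(anglesByFinger) != 5L)
    stop("shape error: anglesByFinger must have 5 columns")
  if (ncol(coupling) != 5L)
    stop("shape error: coupling must have 5 columns")
  if (length(baseline) != nrow(coupling))
    stop("shape error: baseline length must equal nrow(coupling)")
  if (any(coupling < 0)) stop("coupling must be non-negative")
  tl <- nrow(anglesByFinger)
  nc <- nrow(coupling)
  norm <- sweep(anglesByFinger, 2, amplitudePerFinger, "/")
  act <- .saturate(norm)                     # T x 5
  press <- act %*% t(coupling)               # T x C
  press <- sweep(press, 2, baseline, "+")
  if (noiseSd > 0 || driftSd > 0) {
    set.seed(as.integer(seed))
    if (driftSd > 0) {
      drift <- apply(matrix(rnorm(tl * nc, 0, driftSd), tl, nc), 2, cumsum)
      press <- press + drift
    }
    if (noiseSd > 0)
      press <- press + matrix(rnorm(tl * nc, 0, noiseSd), tl, nc)
  }
  press
}

#' Simulate one wristband trial
#'
#' One trial: five contiguous equal-length segments in thumb-to-pinky order;
#' within each segment only the active finger moves, following a
#' raised-cosine trajectory whose frequency is drawn from
#' \code{flexionFreqRange} and whose phase is uniform (self-selected pace).
#'
#' @param config a [SimConfig-class].
#' @param subjectIdx,trialIdx 1-based subject and trial indices; they enter
#'   the seed derivation, so any trial is reproducible in isolation.
#' @param subject optional precomputed [subjectCoupling()] result (reused
#'   across a subject's trials by [simulateDataset()]).
#' @return an [FmgTrial-class] with \code{5 * secondsPerFinger * sampleRate}
#'   samples.
#' @export
simulateTrial <- function(config, subjectIdx = 1L, trialIdx = 1L,
                          subject = NULL) {
  validObject(config)
  if (is.null(subject)) subject <- subjectCoupling(config, subjectIdx)
  segLen <- as.integer(round(config@secondsPerFinger * config@sampleRate))
  tl <- 5L * segLen
  seed <- .deriveSeed(config@seed, subjectIdx, trialIdx)
  set.seed(seed)
  # self-selected pace: the subject's preferred frequency with small
  # per-segment variation, quantised so each segment holds a whole number
  # of flexion cycles (the finger starts from and returns to rest, so
  # angles and pressures are continuous at segment boundaries)
  us <- subject$pace + runif(5, -0.02, 0.02)
  freqs <- pmax(1, round(us * config@secondsPerFinger)) /
    config@secondsPerFinger
  phases <- rep(0, 5)
  noiseSeed <- sample.int(2147483646L, 1)
  anglesByFinger <- matrix(0, nrow = tl, ncol = 5)
  labels <- rep(0:4, each = segLen)
  for (f in 1:5) {
    amp <- config@amplitudePerFinger[f] * subject$amplitudeScale
    th <- angleTrajectory(f - 1L, config@secondsPerFinger,
                          config@sampleRate, amp, freqs[f], phases[f])
    rows <- ((f - 1L) * segLen + 1L):(f * segLen)
    anglesByFinger[rows, f] <- th
  }
  press <- sensorResponse(anglesByFinger, subject$coupling,
                          subject$baseline, config@noiseSd, config@driftSd,
                          seed = noiseSeed,
                          amplitudePerFinger = config@amplitudePerFinger *
                            subject$amplitudeScale)
  angles <- anglesByFinger[cbind(seq_len(tl), labels + 1L)]
  colnames(press) <- paste0("s", seq_len(config@nChannels))
  new("FmgTrial",
      subjectId = sprintf("S%02d", subjectIdx),
      trialId = sprintf("T%02d", trialIdx),
      pressures = press,
      labels = as.integer(labels),
      angles = angles,
      sampleRate = config@sampleRate)
}

#' Simulate a full cohort
#'
#' Generates \code{nSubjects x nTrialsPerSubject} trials. Each subject's
#' coupling matrix, baseline and amplitude attenuation are drawn once and
#' reused across that subject's trials (inter-subject variability, intra-
#' subject stability); per-trial frequency, phase, drift and noise vary.
#' Deterministic for a fixed config.
#'
#' @param config a [SimConfig-class].
#' @return an [FmgDataset-class] of \code{nSubjects * nTrialsPerSubject}
#'   trials, ordered subject-major.
#' @examples
#' ds <- simulateDataset(simConfig(nSubjects = 1, nTrialsPerSubject = 2))
#' length(ds)  # 2
#' @export
simulateDataset <- function(config) {
  validObject(config)
  trials <- vector("list", config@nSubjects * config@nTrialsPerSubject)
  k <- 1L
  for (s in seq_len(config@nSubjects)) {
    subj <- subjectCoupling(config, s)
    for (tr in seq_len(config@nTrialsPerSubject)) {
      trials[[k]] <- simulateTrial(config, s, tr, subject = subj)
      k <- k + 1L
    }
  }
  new("FmgDataset", trials = trials, simConfig = config)
}

#' Split a dataset by subject
#'
#' @param dataset an [FmgDataset-class].
#' @return named list mapping subjectId to the list of that subject's
#'   trials, in trial order.
#' @export
splitBySubject <- function(dataset) {
  ids <- vapply(trials(dataset), subjectId, character(1))
  split(trials(dataset), factor(ids, levels = unique(ids)))
}
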