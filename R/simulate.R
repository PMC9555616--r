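#' @include AllClasses.R constants.R probe.R
NULL

#' Default systemic-activity simulation parameters
#'
#' Three narrow-band physiological oscillators shared across the scalp --
#' Mayer wave (~0.10 Hz), respiration (~0.25 Hz) and cardiac pulsation
#' (~1.1 Hz) -- with inter-channel coherence decaying over
#' \code{spatialScale}, plus per-channel 1/f noise. Amplitudes are on the
#' oxyhemoglobin concentration scale (uM); deoxyhemoglobin systemic activity
#' is a positively co-fluctuating scaled copy.
#'
#' @param components data.frame with columns name, freq (Hz), amplitude (uM),
#'   bandwidth (Hz) and optionally nSources (number of semi-independent
#'   sources per band, emulating distinct vascular territories; the band
#'   amplitude is split across sources).
#' @param spatialScale spatial coherence scale in mm.
#' @param phaseJitter sd (rad) of the spatially correlated per-channel phase
#'   offsets; larger values make the systemic field more heterogeneous.
#' @param amplitudeJitter relative sd of the per-channel amplitude weights.
#' @param noiseSD 1/f noise standard deviation in uM.
#' @param sdcNoiseFactor noise multiplier for SDCs (idiosyncratic scalp
#'   vasculature).
#' @param taskEvokedRegular,taskEvokedSdc amplitude (uM) of the task-locked
#'   systemic waveform for regular channels / SDCs; 0 disables it.
#' @param hbrRatio deoxy/oxy systemic amplitude ratio.
#' @param hbrPhaseLag rad; phase lag of deoxy- behind oxyhemoglobin
#'   oscillations.
#' @param baselineIntensity raw intensity baseline (detector units).
#' @return an [SAParams-class] object.
#' @export
saParams <- function(components = data.frame(
                       name = c("vlf", "mayer", "respiratory", "cardiac"),
                       freq = c(0.04, 0.10, 0.25, 1.10),
                       amplitude = c(7.0, 5.0, 2.0, 1.0),
                       bandwidth = c(0.01, 0.015, 0.04, 0.08),
                       nSources = c(3L, 2L, 1L, 1L)),
                     spatialScale = 45, phaseJitter = 2.0,
                     amplitudeJitter = 0.4, noiseSD = 0.5,
                     sdcNoiseFactor = 2, taskEvokedRegular = 0,
                     taskEvokedSdc = 0, hbrRatio = 0.4,
                     hbrPhaseLag = 0.9, baselineIntensity = 1000) {
  new("SAParams", components = components, spatialScale = spatialScale,
      phaseJitter = phaseJitter, amplitudeJitter = amplitudeJitter,
      noiseSD = noiseSD, sdcNoiseFactor = sdcNoiseFactor,
      taskEvokedRegular = taskEvokedRegular,
      taskEvokedSdc = taskEvokedSdc, hbrRatio = hbrRatio,
      hbrPhaseLag = hbrPhaseLag, baselineIntensity = baselineIntensity)
}

#' Draw a blocked-design trial schedule
#'
#' Trials of \code{taskDuration} seconds preceded and followed by rest
#' periods drawn uniformly from \code{restRange}; the leading rest doubles as
#' the pre-stimulus baseline.
#'
#' @param task task label (one of SIM, ME_LEFT, ME_RIGHT, MI).
#' @param nTrials number of trials (>= 1).
#' @param seed integer seed; identical seeds give identical schedules.
#' @param taskDuration task block length in seconds.
#' @param restRange inter-trial rest range in seconds.
#' @return a [TrialSchedule-class].
#' @examples
#' makeTrialSchedule("SIM", 5, seed = 7)
#' @export
makeTrialSchedule <- function(task = c("SIM", "ME_LEFT", "ME_RIGHT", "MI"),
                              nTrials, seed, taskDuration = 15,
                              restRange = c(18, 22)) {
  task <- match.arg(task)
  if (nTrials < 1) stop("nTrials must be >= 1")
  withr::with_seed(seed, {
    rests <- stats::runif(nTrials, restRange[1], restRange[2])
    onsets <- cumsum(rests + c(0, rep(taskDuration, nTrials - 1)))
  })
  new("TrialSchedule", task = task,
      events = data.frame(onset = onsets, duration = taskDuration,
                          label = task),
      taskDuration = taskDuration, seed = as.integer(seed))
}

#' Draw a multi-task session schedule
#'
#' Interleaves trials of several tasks in pseudorandom order with jittered
#' rest, a short instruction cue before every trial, and a longer break
#' every \code{breakEvery} trials -- the structure of a real motor
#' execution / imagery session.
#'
#' @param tasks task labels to interleave.
#' @param nTrialsEach trials per task.
#' @param seed integer seed.
#' @param taskDuration trial length (s).
#' @param restRange rest jitter range (s).
#' @param instructionDuration instruction cue length (s), shown 3 s before
#'   each onset.
#' @param breakDuration break length (s).
#' @param breakEvery insert a break after this many trials.
#' @return a [TrialSchedule-class] with task label "SESSION".
#' @export
makeSessionSchedule <- function(tasks = c("ME_LEFT", "ME_RIGHT", "MI"),
                                nTrialsEach = 5, seed, taskDuration = 15,
                                restRange = c(18, 22),
                                instructionDuration = 2,
                                breakDuration = 15, breakEvery = 6) {
  labels <- withr::with_seed(seed, sample(rep(tasks, nTrialsEach)))
  rests <- withr::with_seed(seed + 1L,
    stats::runif(length(labels), restRange[1], restRange[2]))
  ev <- list(); t <- 0
  for (k in seq_along(labels)) {
    t <- t + rests[k]
    ev[[length(ev) + 1L]] <- data.frame(
      onset = t - 3, duration = instructionDuration, label = "instruction")
    ev[[length(ev) + 1L]] <- data.frame(
      onset = t, duration = taskDuration, label = labels[k])
    t <- t + taskDuration
    if (k %% breakEvery == 0L && k < length(labels)) {
      ev[[length(ev) + 1L]] <- data.frame(
        onset = t, duration = breakDuration, label = "break")
      t <- t + breakDuration
    }
  }
  events <- do.call(rbind, ev)
  events <- events[order(events$onset), ]
  rownames(events) <- NULL
  new("TrialSchedule", task = "SESSION", events = events,
      taskDuration = taskDuration, seed = as.integer(seed))
}

#' Total recording time needed to cover a schedule
#'
#' Last trial offset plus the post-stimulus epoch window and a small pad.
#' @param schedule a [TrialSchedule-class].
#' @param pad extra seconds appended after the final epoch window.
#' @return duration in seconds.
#' @export
scheduleDuration <- function(schedule, pad = 5) {
  max(trialOnsets(schedule)) + 25 + pad
}

# draw from a zero-mean Gaussian process over channel positions
.gpDraw <- function(K) {
  L <- chol(K + 1e-8 * diag(nrow(K)))
  drop(crossprod(L, stats::rnorm(nrow(K))))
}

# 1/f-shaped noise series with standard deviation sd: white noise spectrally
# reweighted by 1/sqrt(f) (symmetric weights keep the series real)
.pinkNoise <- function(n, sd) {
  if (sd == 0) return(numeric(n))
  X <- stats::fft(stats::rnorm(n))
  f <- (seq_len(n) - 1) / n
  fr <- pmin(f, 1 - f)
  shape <- 1 / sqrt(pmax(fr, 1 / n))
  shape[1] <- 0
  x <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  sd * (x - mean(x)) / stats::sd(x)
}

# oscillatory systemic layer for both species: channels x samples, uM.
# The deoxyhemoglobin copy is amplitude-scaled by hbrRatio and phase-lagged
# by hbrPhaseLag (venous transit delays make HbR oscillations trail HbO).
.systemicLayer <- function(D, n, fs, params) {
  nCh <- nrow(D)
  hbo <- matrix(0, nCh, n)
  hbr <- matrix(0, nCh, n)
  K <- exp(-D^2 / (2 * params@spatialScale^2))
  tvec <- (seq_len(n) - 1) / fs
  for (k in seq_len(nrow(params@components))) {
    cp <- params@components[k, ]
    if (cp$amplitude == 0) next
    nSrc <- if ("nSources" %in% names(cp)) cp$nSources else 1L
    for (src in seq_len(nSrc)) {
      phi0 <- stats::runif(1, 0, 2 * pi)
      # phase diffusion gives the component its spectral linewidth
      drift <- cumsum(stats::rnorm(n, 0, sqrt(2 * pi * cp$bandwidth / fs)))
      psi <- params@phaseJitter * .gpDraw(K)   # spatially correlated phases
      w <- 1 + params@amplitudeJitter * .gpDraw(K)
      carrier <- 2 * pi * cp$freq * tvec + phi0 + drift
      a <- cp$amplitude / sqrt(nSrc) * w
      hbo <- hbo + a * cos(outer(psi, carrier, "+"))
      hbr <- hbr + params@hbrRatio * a *
        cos(outer(psi, carrier, "+") - params@hbrPhaseLag)
    }
  }
  list(hbo = hbo, hbr = hbr)
}

.noiseLayer <- function(sdPerChannel, n) {
  M <- matrix(0, length(sdPerChannel), n)
  for (i in seq_along(sdPerChannel))
    if (sdPerChannel[i] > 0) M[i, ] <- .pinkNoise(n, sdPerChannel[i])
  M
}

# wrap a concentration layer into a RawRecording via the forward mBLL
.concToRecording <- function(hbo, hbr, layout, age, params) {
  ch <- layout@channels
  assays <- lapply(names(.WAVELENGTHS), function(wl) {
    od <- .forwardOD(hbo, hbr, wl, ch$distance, age)
    params@baselineIntensity * exp(-od)
  })
  names(assays) <- names(.WAVELENGTHS)
  se <- SummarizedExperiment(
    assays = assays,
    rowData = DataFrame(ch, pruned = FALSE),
    metadata = list(fs = .FS, layout = layout, age = age, saParams = params))
  rownames(se) <- rownames(ch)
  new("RawRecording", se)
}

#' Simulate a resting-state dual-wavelength recording
#'
#' Generates the hemodynamic baseline of the synthetic cohort: spatially
#' coherent narrow-band systemic oscillations (shared between SDCs and
#' regular channels, coherence decaying with inter-channel distance) plus
#' per-channel 1/f noise, converted to raw light intensity through the
#' forward modified Beer-Lambert law so that preprocessing inverts it
#' exactly up to noise.
#'
#' @param layout a [ProbeLayout-class].
#' @param duration recording length in seconds (> 30).
#' @param params an [SAParams-class] object.
#' @param age subject age in years (feeds the pathlength factor).
#' @param seed integer seed.
#' @return a [RawRecording-class] (channels x samples at 7.8125 Hz).
#' @examples
#' rec <- simulateRestRecording(makeProbeLayout(), 60, saParams(),
#'                              age = 65, seed = 1)
#' dim(rec)
#' @export
simulateRestRecording <- function(layout, duration, params = saParams(),
                                  age = 65, seed = 1) {
  if (duration <= 30) stop("duration must exceed 30 s")
  n <- floor(duration * .FS)
  D <- channelDistances(layout, "euclidean", "all")
  sdCh <- params@noiseSD *
    ifelse(layout@channels$type == "sdc", params@sdcNoiseFactor, 1)
  layers <- withr::with_seed(seed, {
    osc <- .systemicLayer(D, n, .FS, params)
    # each species gets its own 1/f noise so the two are co-fluctuating
    # but not perfectly collinear
    list(osc = osc,
         noiseHbo = .noiseLayer(sdCh, n),
         noiseHbr = .noiseLayer(sdCh, n))
  })
  hbo <- layers$osc$hbo + layers$noiseHbo
  hbr <- layers$osc$hbr + params@hbrRatio * layers$noiseHbr
  .concToRecording(hbo, hbr, layout, age, params)
}

# unit-peak gamma waveform for task-locked systemic activity
.taskSAWaveform <- function(tvec, shape = 6, rate = 1) {
  g <- stats::dgamma(tvec, shape = shape, rate = rate)
  g / max(g)
}

#' Add task-evoked systemic activity to a recording
#'
#' Superimposes a gamma-shaped waveform, time-locked to every trial onset,
#' on the hemodynamic layer of all channels: regular channels scaled by
#' \code{taskEvokedRegular}, SDCs by \code{taskEvokedSdc} (both uM, with
#' 10\% per-channel amplitude jitter). This emulates scalp blood-flow
#' responses that mimic brain activation and lets correction methods be
#' stress-tested against systemic task confounds. Zero amplitudes return
#' the input unchanged.
#'
#' @param recording a [RawRecording-class].
#' @param schedule a [TrialSchedule-class] fitting inside the recording.
#' @param params an [SAParams-class]; only the task-evoked amplitudes,
#'   hbrRatio and baseline intensity are used.
#' @param seed integer seed for the amplitude jitter.
#' @return a [RawRecording-class].
#' @export
addTaskEvokedSA <- function(recording, schedule, params, seed = 1) {
  if (params@taskEvokedRegular == 0 && params@taskEvokedSdc == 0)
    return(recording)
  n <- ncol(recording); fs <- samplingRate(recording)
  onsets <- trialOnsets(schedule)
  if (max(onsets) * fs + 1 > n)
    stop("schedule overruns the recording")
  tvec <- (seq_len(n) - 1) / fs
  wave <- numeric(n)
  for (on in onsets) {
    idx <- which(tvec >= on & tvec < on + 30)
    wave[idx] <- wave[idx] + .taskSAWaveform(tvec[idx] - on)
  }
  ch <- rowData(recording)
  amp <- ifelse(ch$type == "sdc", params@taskEvokedSdc,
                params@taskEvokedRegular)
  amp <- amp * withr::with_seed(seed, 1 + 0.1 * stats::rnorm(nrow(recording)))
  hbo <- outer(amp, wave)
  hbr <- params@hbrRatio * hbo
  age <- subjectAge(recording)
  out <- recording
  for (wl in names(.WAVELENGTHS)) {
    od <- .forwardOD(hbo, hbr, wl, ch$distance, age)
    SummarizedExperiment::assay(out, wl) <-
      assay(recording, wl) * exp(-od)
  }
  out
}
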