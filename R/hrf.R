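#' @include AllClasses.R constants.R
NULL

#' Canonical hemodynamic response function template
#'
#' Double-gamma canonical shape: a response gamma peaking at \code{peak}
#' seconds minus an undershoot gamma peaking \code{undershootDelay} seconds
#' later, weighted by \code{undershootRatio}; the template is renormalised
#' to unit maximum and starts at 0 at t = 0.
#'
#' @param fs sampling rate (Hz).
#' @param duration template length in seconds (>= peak).
#' @param peak peak latency in seconds.
#' @param undershootDelay peak-to-undershoot latency in seconds.
#' @param undershootRatio undershoot amplitude relative to the response.
#' @return numeric template of \code{round(duration * fs)} samples with
#'   maximum 1.
#' @examples
#' h <- canonicalHRF(7.8125, 30)
#' which.max(h) / 7.8125   # ~6 s
#' @export
canonicalHRF <- function(fs, duration, peak = 6, undershootDelay = 10,
                         undershootRatio = 1 / 6) {
  if (duration < peak) stop("duration must be >= peak latency")
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  # gamma with rate 1 peaks at shape - 1
  h <- stats::dgamma(t, shape = peak + 1, rate = 1) -
    undershootRatio * stats::dgamma(t, shape = peak + undershootDelay + 1,
                                    rate = 1)
  h / max(h)
}

#' Canonical-HRF injection specification
#'
#' @param amplitudes named numeric; names are regular-channel ids, values
#'   the oxyhemoglobin amplitude in uM applied to the unit-peak template.
#'   The default reproduces the semisimulation design: 10 uM into channel 6
#'   (100\%) and 5 uM into channel 8 (50\%) of ROI M1 left.
#' @param hbrFraction deoxyhemoglobin amplitude = -amplitude * hbrFraction.
#' @param peak template peak latency (s).
#' @param duration template length (s).
#' @return an [HRFSpec-class].
#' @export
hrfSpec <- function(amplitudes = c("6" = 10, "8" = 5), hbrFraction = 1 / 3,
                    peak = 6, duration = 30) {
  new("HRFSpec", peak = peak, duration = duration,
      amplitudes = amplitudes, hbrFraction = hbrFraction)
}

#' Inject canonical HRFs at trial onsets (semisimulation)
#'
#' For every trial onset the unit-peak canonical template scaled by the
#' channel amplitude is added to the oxyhemoglobin series and the sign-
#' flipped template scaled by \code{amplitude * hbrFraction} to the
#' deoxyhemoglobin series of the specified regular channels; all other
#' channels are untouched. This turns resting data into semisimulated task
#' data with known ground truth.
#'
#' @param hemo a [HemoSeries-class] (concentration units, uM).
#' @param schedule a [TrialSchedule-class] fitting inside the recording.
#' @param spec an [HRFSpec-class].
#' @return a [HemoSeries-class].
#' @export
injectCanonicalHRF <- function(hemo, schedule, spec = hrfSpec()) {
  stopifnot(is(hemo, "HemoSeries"), is(spec, "HRFSpec"))
  if (!length(spec@amplitudes)) return(hemo)
  fs <- samplingRate(hemo); n <- ncol(hemo)
  tpl <- canonicalHRF(fs, spec@duration, spec@peak)
  onsets <- trialOnsets(schedule)
  hbo <- assay(hemo, "hbo"); hbr <- assay(hemo, "hbr")
  for (chName in names(spec@amplitudes)) {
    row <- .rowOfChannel(hemo, as.integer(chName), "regular")
    if (!length(row)) stop("amplitude given for unknown channel ", chName)
    a <- spec@amplitudes[[chName]]
    for (on in onsets) {
      i0 <- round(on * fs) + 1L
      idx <- i0:(i0 + length(tpl) - 1L)
      if (max(idx) > n) stop("onset + template overruns the recording")
      hbo[row, idx] <- hbo[row, idx] + a * tpl
      hbr[row, idx] <- hbr[row, idx] - a * spec@hbrFraction * tpl
    }
  }
  .rebuildSeries(hemo, list(hbo = hbo, hbr = hbr), "HemoSeries")
}
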