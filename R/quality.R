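#' @include AllClasses.R constants.R
NULL

# windowed cardiac-coupling metrics for one channel
.windowQuality <- function(s1, s2, nWin) {
  nw <- floor(length(s1) / nWin)
  sci <- psp <- numeric(nw)
  for (k in seq_len(nw)) {
    idx <- ((k - 1) * nWin + 1):(k * nWin)
    a <- s1[idx]; b <- s2[idx]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      sci[k] <- 0; psp[k] <- 0; next
    }
    a <- (a - mean(a)) / stats::sd(a)
    b <- (b - mean(b)) / stats::sd(b)
    sci[k] <- stats::cor(a, b)
    # peak spectral power: fraction of cross-correlation spectral power
    # concentrated at the dominant frequency
    cc <- stats::convolve(a, b, conj = TRUE, type = "circular") / nWin
    pw <- Mod(stats::fft(cc))
    psp[k] <- if (sum(pw) > 0) max(pw) / sum(pw) else 0
  }
  list(sci = sci, psp = psp)
}

#' Assess channel quality via scalp coupling index and peak spectral power
#'
#' Both wavelengths of every channel are band-passed to the cardiac band
#' (0.5-2.5 Hz) and cut into non-overlapping windows. Per window the scalp
#' coupling index (SCI) is the correlation of the two wavelengths' filtered
#' signals and the peak spectral power (PSP) is the spectral concentration
#' of their cross-correlation; a window passes iff SCI >= \code{sciThr} and
#' PSP >= \code{pspThr}. A channel's quality fraction \code{q} is the share
#' of passing windows and the channel is pruned iff \code{q < qThr}. A
#' channel with good optode-scalp coupling shows the cardiac pulse
#' coherently at both wavelengths; decoupled channels show independent
#' noise.
#'
#' @param raw a [RawRecording-class] of at least 30 s.
#' @param sciThr,pspThr,qThr decision thresholds.
#' @param windowSec window length in seconds (non-overlapping).
#' @param cardiacBand band-pass limits in Hz.
#' @return a [QualityReport-class].
#' @export
assessChannelQuality <- function(raw, sciThr = 0.6, pspThr = 0.1,
                                 qThr = 0.65, windowSec = 5,
                                 cardiacBand = c(0.5, 2.5)) {
  stopifnot(is(raw, "RawRecording"))
  fs <- samplingRate(raw)
  n <- ncol(raw)
  nWin <- floor(windowSec * fs)
  if (n < nWin) stop("recording too short for one quality window")
  nyq <- fs / 2
  bp <- signal::butter(3, pmin(cardiacBand / nyq, 0.99), type = "pass")
  I1 <- assay(raw, "wl760"); I2 <- assay(raw, "wl850")
  ch <- rowData(raw)
  zscore <- function(v) {
    s <- stats::sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  tb <- lapply(seq_len(nrow(raw)), function(i) {
    s1 <- signal::filtfilt(bp, zscore(I1[i, ]))
    s2 <- signal::filtfilt(bp, zscore(I2[i, ]))
    wq <- .windowQuality(s1, s2, nWin)
    pass <- wq$sci >= sciThr & wq$psp >= pspThr
    data.frame(row = i, channel = ch$channel[i], type = ch$type[i],
               sci = stats::median(wq$sci), psp = stats::median(wq$psp),
               q = mean(pass))
  })
  tb <- do.call(rbind, tb)
  tb$pruned <- tb$q < qThr
  new("QualityReport", table = tb,
      thresholds = c(sci = sciThr, psp = pspThr, q = qThr),
      windowSec = windowSec)
}
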