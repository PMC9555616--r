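#' @include AllClasses.R constants.R
NULL

# rebuild a series object of class `cls` from a template, replacing assays
.rebuildSeries <- function(template, assays, cls) {
  se <- SummarizedExperiment(
    assays = assays, rowData = rowData(template),
    metadata = metadata(template))
  rownames(se) <- rownames(template)
  new(cls, se)
}

#' Convert raw intensity to optical density changes
#'
#' Per channel and wavelength, \eqn{\Delta OD(t) = -\ln(I(t) / \bar I)} with
#' the channel temporal mean as reference intensity. Scale-invariant in the
#' intensity; note the output is not exactly zero-mean (the log of the mean
#' is not the mean of the log).
#'
#' @param raw a [RawRecording-class] (all intensities positive).
#' @return an [ODSeries-class].
#' @export
intensityToOD <- function(raw) {
  stopifnot(is(raw, "RawRecording"))
  assays <- lapply(names(.WAVELENGTHS), function(wl) {
    I <- assay(raw, wl)
    if (any(I <= 0)) stop("intensities must be positive")
    -log(I / rowMeans(I))
  })
  names(assays) <- names(.WAVELENGTHS)
  .rebuildSeries(raw, assays, "ODSeries")
}

# temporal derivative distribution repair of one series
.tddr1 <- function(y, fs, lowpassHz = 0.5, tune = 4.685,
                   tol = 1e-8, maxIter = 50L) {
  n <- length(y)
  if (n < 3L || !all(is.finite(y))) return(y)
  if (max(y) == min(y)) return(y)
  # repair operates on the slow band; the fast band is restored afterwards
  nyq <- fs / 2
  if (lowpassHz < nyq) {
    bf <- signal::butter(3, lowpassHz / nyq, type = "low")
    ylow <- signal::filtfilt(bf, y)
  } else ylow <- y
  yhigh <- y - ylow
  d <- diff(ylow)
  w <- rep(1, length(d)); mu <- 0
  for (iter in seq_len(maxIter)) {
    mu <- sum(w * d) / sum(w)
    dev <- d - mu
    sigma <- 1.4826 * stats::median(abs(dev))
    if (sigma == 0) return(y)
    r <- dev / (tune * sigma)
    wNew <- ifelse(abs(r) < 1, (1 - r^2)^2, 0)
    done <- max(abs(wNew - w)) < tol
    w <- wNew
    if (done) break
  }
  corr <- cumsum(c(0, w * (d - mu)))
  corr <- corr - mean(corr) + mean(ylow)
  corr + yhigh
}

#' Temporal derivative distribution repair (motion-artifact correction)
#'
#' Per channel and wavelength, the temporal derivative of the slow
#' (<= 0.5 Hz) band is iteratively reweighted with Tukey's bisquare
#' (c = 4.685, robust scale 1.4826 x MAD) until the weights stabilise; the
#' repaired series is the cumulative sum of the weighted centred derivatives
#' with the original mean restored, plus the untouched fast band. Motion
#' spikes, which live in the tails of the derivative distribution, are
#' suppressed while smooth signal passes through. Pruned (all-NaN) channels
#' pass through unchanged.
#'
#' @param od an [ODSeries-class].
#' @param lowpassHz cut-off isolating the band being repaired.
#' @param tune Tukey bisquare tuning constant.
#' @param tol convergence tolerance on the weight change.
#' @param maxIter iteration cap.
#' @return an [ODSeries-class].
#' @export
tddr <- function(od, lowpassHz = 0.5, tune = 4.685, tol = 1e-8,
                 maxIter = 50L) {
  stopifnot(is(od, "ODSeries"))
  fs <- samplingRate(od)
  assays <- lapply(names(.WAVELENGTHS), function(wl) {
    M <- assay(od, wl)
    t(apply(M, 1, .tddr1, fs = fs, lowpassHz = lowpassHz, tune = tune,
            tol = tol, maxIter = maxIter))
  })
  names(assays) <- names(.WAVELENGTHS)
  .rebuildSeries(od, assays, "ODSeries")
}

#' Optical density to hemoglobin concentration changes (modified
#' Beer-Lambert law)
#'
#' Per channel and sample the 2x2 extinction system is solved:
#' \deqn{\Delta OD_\lambda = \left(\epsilon_{\lambda,HbO}\Delta[HbO] +
#'   \epsilon_{\lambda,HbR}\Delta[HbR]\right) d \cdot PPF(\lambda)}
#' with the source-detector distance \eqn{d} from the layout, and the
#' partial pathlength factor \eqn{PPF = DPF(\lambda, age) \times PVF},
#' \eqn{PVF = 1/60}. Concentrations are returned in uM.
#'
#' @param od an [ODSeries-class].
#' @param age subject age in years; defaults to the age stored with the
#'   recording.
#' @return a [HemoSeries-class].
#' @export
odToHemoglobin <- function(od, age = subjectAge(od)) {
  stopifnot(is(od, "ODSeries"))
  E <- .extinctionLn()
  Einv <- solve(E)     # species x wavelength
  dists <- rowData(od)$distance
  scaled <- lapply(names(.WAVELENGTHS), function(wl) {
    path <- (dists / 10) * .ppf(.WAVELENGTHS[[wl]], age)
    assay(od, wl) / path
  })
  names(scaled) <- names(.WAVELENGTHS)
  hbo <- Einv["hbo", "wl760"] * scaled$wl760 +
         Einv["hbo", "wl850"] * scaled$wl850
  hbr <- Einv["hbr", "wl760"] * scaled$wl760 +
         Einv["hbr", "wl850"] * scaled$wl850
  .rebuildSeries(od, list(hbo = hbo, hbr = hbr), "HemoSeries")
}

#' Zero-phase Butterworth band-pass of a hemoglobin series
#'
#' Sequential forward-backward (zero-phase) Butterworth passes: low-pass at
#' \code{high} Hz then high-pass at \code{low} Hz, each of design order
#' \code{order}. The defaults isolate the 0.01-0.09 Hz hemodynamic band,
#' rejecting drifts and cardiac/respiratory oscillations. Pruned channels
#' pass through as NaN.
#'
#' @param hemo a [HemoSeries-class].
#' @param low high-pass cut-off (Hz).
#' @param high low-pass cut-off (Hz).
#' @param order Butterworth design order of each pass.
#' @return a [HemoSeries-class].
#' @export
bandpassHemo <- function(hemo, low = 0.01, high = 0.09, order = 2) {
  stopifnot(is(hemo, "HemoSeries"))
  fs <- samplingRate(hemo); nyq <- fs / 2
  if (!(low < high && high < nyq)) stop("need low < high < fs/2")
  lp <- signal::butter(order, high / nyq, type = "low")
  hp <- signal::butter(order, low / nyq, type = "high")
  filt1 <- function(y) {
    if (!all(is.finite(y))) return(y)
    signal::filtfilt(hp, signal::filtfilt(lp, y))
  }
  assays <- lapply(names(assays(hemo)), function(a)
    t(apply(assay(hemo, a), 1, filt1)))
  names(assays) <- names(assays(hemo))
  .rebuildSeries(hemo, assays, "HemoSeries")
}

#' Blank out pruned channels
#'
#' Replaces the rows of channels flagged as pruned in a
#' [QualityReport-class] with NaN in every assay and records the flags in
#' \code{rowData(x)$pruned}. Every downstream operation propagates the NaN.
#'
#' @param x a [FnirsSeries-class] object.
#' @param report a [QualityReport-class] computed on the matching raw
#'   recording.
#' @return the same class as \code{x}.
#' @export
pruneChannels <- function(x, report) {
  stopifnot(is(x, "FnirsSeries"), is(report, "QualityReport"))
  bad <- report@table$row[report@table$pruned]
  if (!length(bad)) return(x)
  assays <- lapply(names(assays(x)), function(a) {
    M <- assay(x, a); M[bad, ] <- NaN; M
  })
  names(assays) <- names(assays(x))
  out <- .rebuildSeries(x, assays, class(x))
  rd <- rowData(out); rd$pruned <- seq_len(nrow(out)) %in% bad
  SummarizedExperiment::rowData(out) <- rd
  out
}
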