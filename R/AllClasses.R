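#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#' @importFrom S4Vectors metadata DataFrame
NULL

#' Probe layout for a motor-cortex fNIRS montage
#'
#' Channel geometry on a template scalp sphere: 16 regular (long-separation,
#' 30 mm) channels grouped into the regions of interest M1 left, M1 right and
#' SMA, plus 8 short-distance channels (SDCs, 8 mm separation) used as
#' extracerebral reference signals. Only inter-position distances are consumed
#' downstream (Gaussian kernel of the global component removal, nearest-SDC
#' mapping of the short separation regression), so positions are idealised
#' 10-5-like coordinates on a sphere.
#'
#' @slot channels data.frame with one row per channel: \code{channel} (id
#'   within type), \code{type} ("regular" or "sdc"), \code{source},
#'   \code{detector}, \code{x}, \code{y}, \code{z} midpoint coordinates in mm,
#'   \code{roi} label, \code{distance} source-detector separation in mm.
#' @slot headRadius sphere radius in mm.
#' @export
setClass("ProbeLayout",
  slots = c(channels = "data.frame", headRadius = "numeric"))

setValidity("ProbeLayout", function(object) {
  ch <- object@channels
  msg <- character()
  need <- c("channel", "type", "source", "detector", "x", "y", "z",
            "roi", "distance")
  if (!all(need %in% names(ch)))
    return(paste("channels must contain columns:", paste(need, collapse = ", ")))
  reg <- ch[ch$type == "regular", ]
  sdc <- ch[ch$type == "sdc", ]
  if (nrow(reg) != 16L) msg <- c(msg, "exactly 16 regular channels required")
  if (nrow(sdc) != 8L) msg <- c(msg, "exactly 8 SDCs required")
  if (!all(reg$roi[match(c(6L, 8L), reg$channel)] == "M1_LEFT"))
    msg <- c(msg, "channels 6 and 8 must belong to ROI M1_LEFT")
  for (r in c("M1_LEFT", "M1_RIGHT", "SMA"))
    if (sum(reg$roi == r) < 2L)
      msg <- c(msg, sprintf("ROI %s must contain >= 2 regular channels", r))
  if (!all(abs(reg$distance - 30) < 1e-9))
    msg <- c(msg, "regular source-detector distance must be 30 mm")
  if (!all(abs(sdc$distance - 8) < 1e-9))
    msg <- c(msg, "SDC source-detector distance must be 8 mm")
  rad <- sqrt(ch$x^2 + ch$y^2 + ch$z^2)
  if (any(abs(rad - object@headRadius) > 1e-6))
    msg <- c(msg, "all positions must lie on the head sphere")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Trial/event schedule of a blocked design
#'
#' Events are task trials (fixed task duration, jittered inter-trial rest)
#' plus optional instruction and break events for multi-task sessions.
#'
#' @slot task primary task label (e.g. "SIM") or "SESSION" for multi-task
#'   schedules.
#' @slot events data.frame with columns \code{onset} (s), \code{duration} (s),
#'   \code{label}.
#' @slot taskDuration task block length in seconds.
#' @slot seed integer seed the schedule was drawn with.
#' @export
setClass("TrialSchedule",
  slots = c(task = "character", events = "data.frame",
            taskDuration = "numeric", seed = "integer"))

setValidity("TrialSchedule", function(object) {
  ev <- object@events
  if (!all(c("onset", "duration", "label") %in% names(ev)))
    return("events must have columns onset, duration, label")
  if (is.unsorted(ev$onset)) return("events must be sorted by onset")
  tr <- ev[!(ev$label %in% c("instruction", "break")), ]
  if (nrow(tr)) {
    if (tr$onset[1L] < 5) return("first trial onset must be >= 5 s")
    if (nrow(tr) > 1L) {
      gap <- tr$onset[-1L] - (tr$onset[-nrow(tr)] + tr$duration[-nrow(tr)])
      if (any(gap < -1e-9)) return("trials must not overlap")
    }
  }
  TRUE
})

#' Systemic-activity simulation parameters
#'
#' Parameterises the physiological interference model of the synthetic
#' cohort: narrow-band oscillators (Mayer wave, respiration, cardiac pulse)
#' shared across the scalp with coherence decaying over a spatial scale,
#' 1/f channel noise, and an optional task-locked systemic waveform.
#'
#' @slot components data.frame: \code{name}, \code{freq} (Hz),
#'   \code{amplitude} (uM, oxyhemoglobin scale), \code{bandwidth} (Hz,
#'   amplitude/phase drift rate).
#' @slot spatialScale mm; e-folding-like scale of inter-channel coherence.
#' @slot phaseJitter rad; standard deviation of the spatially correlated
#'   per-channel phase offsets (controls how heterogeneous the systemic
#'   field is across the scalp).
#' @slot amplitudeJitter relative standard deviation of the spatially
#'   correlated per-channel amplitude weights.
#' @slot noiseSD uM; standard deviation of per-channel 1/f noise.
#' @slot sdcNoiseFactor multiplier on \code{noiseSD} for SDCs, modelling
#'   the idiosyncratic superficial vasculature fluctuations short channels
#'   pick up but long channels largely average out.
#' @slot taskEvokedRegular,taskEvokedSdc uM; amplitude of the task-locked
#'   systemic waveform added to regular channels / SDCs (0 disables).
#' @slot hbrRatio scale of deoxyhemoglobin systemic activity relative to
#'   oxyhemoglobin (positive co-fluctuation).
#' @slot hbrPhaseLag rad; phase by which deoxyhemoglobin oscillations trail
#'   oxyhemoglobin (venous transit delay).
#' @slot baselineIntensity arbitrary detector units for the simulated raw
#'   intensity baseline.
#' @export
setClass("SAParams",
  slots = c(components = "data.frame", spatialScale = "numeric",
            phaseJitter = "numeric", amplitudeJitter = "numeric",
            noiseSD = "numeric", sdcNoiseFactor = "numeric",
            taskEvokedRegular = "numeric",
            taskEvokedSdc = "numeric", hbrRatio = "numeric",
            hbrPhaseLag = "numeric", baselineIntensity = "numeric"))

setValidity("SAParams", function(object) {
  cp <- object@components
  if (!all(c("name", "freq", "amplitude", "bandwidth") %in% names(cp)))
    return("components must have columns name, freq, amplitude, bandwidth")
  if (any(cp$amplitude < 0)) return("component amplitudes must be >= 0")
  if (any(cp$freq <= 0)) return("component frequencies must be positive")
  if (object@noiseSD < 0) return("noiseSD must be >= 0")
  TRUE
})

# ---- SummarizedExperiment-backed signal containers --------------------------

#' Virtual parent of the three signal stages
#'
#' Channels x samples matrices as assays of a SummarizedExperiment. Row
#' metadata carries the channel table of the [ProbeLayout-class]; assay-wide
#' metadata carries the sampling rate (Hz), the layout object and the subject
#' age. The three stages are raw intensity ([RawRecording-class]), optical
#' density ([ODSeries-class]) and hemoglobin concentration
#' ([HemoSeries-class]).
#'
#' @export
setClass("FnirsSeries", contains = c("SummarizedExperiment", "VIRTUAL"))

.validFnirsSeries <- function(object) {
  md <- metadata(object)
  if (is.null(md$fs) || !is.numeric(md$fs) || md$fs <= 0)
    return("metadata(x)$fs must be a positive sampling rate")
  if (!is(md$layout, "ProbeLayout"))
    return("metadata(x)$layout must be a ProbeLayout")
  if (nrow(object) != nrow(md$layout@channels))
    return("row count must equal the layout channel count")
  TRUE
}
setValidity("FnirsSeries", .validFnirsSeries)

#' Raw dual-wavelength intensity recording
#'
#' Assays \code{wl760} and \code{wl850} hold light intensity (positive,
#' arbitrary detector units) for every channel at 7.8125 Hz.
#' @export
setClass("RawRecording", contains = "FnirsSeries")

setValidity("RawRecording", function(object) {
  if (!all(c("wl760", "wl850") %in% names(assays(object))))
    return("assays wl760 and wl850 required")
  for (a in c("wl760", "wl850"))
    if (any(!is.finite(assay(object, a))) || any(assay(object, a) <= 0))
      return("intensities must be positive and finite")
  TRUE
})

#' Optical density change series
#'
#' Assays \code{wl760} and \code{wl850} hold optical density changes relative
#' to the channel temporal mean intensity (natural logarithm). Pruned
#' channels are all-NaN rows flagged in \code{rowData(x)$pruned}.
#' @export
setClass("ODSeries", contains = "FnirsSeries")

setValidity("ODSeries", function(object) {
  if (!all(c("wl760", "wl850") %in% names(assays(object))))
    return("assays wl760 and wl850 required")
  TRUE
})

#' Hemoglobin concentration change series
#'
#' Assays \code{hbo} and \code{hbr} hold oxy-/deoxyhemoglobin concentration
#' changes in micromolar obtained through the modified Beer-Lambert law.
#' @export
setClass("HemoSeries", contains = "FnirsSeries")

setValidity("HemoSeries", function(object) {
  if (!all(c("hbo", "hbr") %in% names(assays(object))))
    return("assays hbo and hbr required")
  if (!identical(dim(assay(object, "hbo")), dim(assay(object, "hbr"))))
    return("hbo and hbr must share dimensions")
  TRUE
})

# ---- quality / correction / fitting results ---------------------------------

#' Channel quality report (scalp coupling index / peak spectral power)
#'
#' @slot table data.frame per channel: \code{row} (row index in the
#'   recording), \code{channel}, \code{type}, \code{sci} (median windowed
#'   SCI), \code{psp} (median windowed PSP), \code{q} fraction of windows
#'   passing both thresholds, \code{pruned}.
#' @slot thresholds named numeric: sci, psp, q.
#' @slot windowSec quality window length in seconds (non-overlapping).
#' @export
setClass("QualityReport",
  slots = c(table = "data.frame", thresholds = "numeric",
            windowSec = "numeric"))

setValidity("QualityReport", function(object) {
  tb <- object@table
  if (any(tb$q < 0 | tb$q > 1, na.rm = TRUE)) return("q must lie in [0, 1]")
  if (any(abs(tb$sci) > 1 + 1e-9, na.rm = TRUE))
    return("sci must lie in [-1, 1]")
  TRUE
})

#' Canonical-HRF injection specification
#'
#' @slot peak peak latency of the canonical HRF in seconds.
#' @slot duration template length in seconds.
#' @slot amplitudes named numeric; names are regular channel ids, values the
#'   oxyhemoglobin amplitude in uM (unit-peak template scaling).
#' @slot hbrFraction deoxyhemoglobin amplitude = -amplitude * hbrFraction.
#' @export
setClass("HRFSpec",
  slots = c(peak = "numeric", duration = "numeric",
            amplitudes = "numeric", hbrFraction = "numeric"))

#' Gaussian spatial kernel of the global component removal
#'
#' @slot G row-normalised kernel (rows sum to 1).
#' @slot Graw unnormalised kernel exp(-D^2 / (2 sigma^2)).
#' @slot D great-circle angular distance matrix in degrees.
#' @slot sigma kernel width in degrees.
#' @export
setClass("KernelMatrix",
  slots = c(G = "matrix", Graw = "matrix", D = "matrix", sigma = "numeric"))

setValidity("KernelMatrix", function(object) {
  if (!isTRUE(all.equal(object@D, t(object@D)))) return("D must be symmetric")
  if (any(object@Graw < 0)) return("kernel must be non-negative")
  if (any(abs(rowSums(object@G) - 1) > 1e-8))
    return("rows of normalised kernel must sum to 1")
  TRUE
})

#' Result of a systemic-activity correction
#'
#' @slot method one of NO_SAC, CAR, GCR, SSR, GLM_ALL, GLM_BH.
#' @slot corrected the corrected [HemoSeries-class].
#' @slot diagnostics method-specific list (CAR: subtracted mean traces; GCR:
#'   global component; SSR: per-channel alpha and SDC mapping; GLM: SDC beta
#'   tables).
#' @export
setClass("CorrectionResult",
  slots = c(method = "character", corrected = "HemoSeries",
            diagnostics = "list"))

setValidity("CorrectionResult", function(object) {
  ok <- c("NO_SAC", "CAR", "GCR", "SSR", "GLM_ALL", "GLM_BH")
  if (!object@method %in% ok)
    return(paste("method must be one of", paste(ok, collapse = ", ")))
  TRUE
})

#' General linear model fit (ordinary or AR-prewhitened robust least squares)
#'
#' @slot design samples x regressors matrix (original, unwhitened).
#' @slot betas regressors x series coefficient matrix.
#' @slot se standard errors, same shape as betas.
#' @slot residuals samples x series residual matrix; on the prewhitened scale
#'   for the AR_IRLS solver (leading max-AR-order rows are NA), original scale
#'   for OLS.
#' @slot arOrders per-series selected AR order (0 for OLS).
#' @slot arCoefs list of per-series AR coefficient vectors.
#' @slot weights list of per-series robust weights (empty for OLS).
#' @slot solver "OLS" or "AR_IRLS".
#' @slot df per-series residual degrees of freedom.
#' @export
setClass("GLMFit",
  slots = c(design = "matrix", betas = "matrix", se = "matrix",
            residuals = "matrix", arOrders = "integer", arCoefs = "list",
            weights = "list", solver = "character", df = "numeric"))

#' Task-level GLM over all channels of a recording
#'
#' @slot fits list with per-species [GLMFit-class] objects (hbo, hbr).
#' @slot betas data.frame: channel, species, regressor, beta, se, t.
#' @slot mode "SIM" (single all-onsets regressor) or "REAL" (per-task
#'   regressors plus instruction and break regressors).
#' @export
setClass("TaskGLMFit",
  slots = c(fits = "list", betas = "data.frame", mode = "character"))

#' Baseline-corrected single-trial epochs
#'
#' Window [-5, 25) s around trial onsets, baseline corrected by the mean over
#' [-5, 0) s; arrays are trials x samples x channels.
#'
#' @slot hbo,hbr numeric arrays (trials x samples x channels), uM.
#' @slot time within-epoch time axis in seconds (0 = onset).
#' @slot fs sampling rate in Hz.
#' @slot channels channel row indices of the source series.
#' @slot onsets onsets (s) of the trials retained.
#' @export
setClass("Epochs",
  slots = c(hbo = "array", hbr = "array", time = "numeric", fs = "numeric",
            channels = "integer", onsets = "numeric"))

#' Jeffreys-Zellner-Siow Bayes-factor t-test result
#'
#' @slot bf10 Bayes factor for H1 over H0 (may overflow to Inf for
#'   overwhelming evidence; logBF10 stays finite).
#' @slot logBF10 natural log of the Bayes factor.
#' @slot t t statistic.
#' @slot n sample size (pairs for the paired mode).
#' @slot df degrees of freedom.
#' @slot cauchyScale Cauchy prior scale on the effect size.
#' @slot mode "one_sample" or "paired".
#' @slot degenerate TRUE when the data had zero variance.
#' @export
setClass("BayesResult",
  slots = c(bf10 = "numeric", logBF10 = "numeric", t = "numeric",
            n = "numeric", df = "numeric", cauchyScale = "numeric",
            mode = "character", degenerate = "logical"))

setValidity("BayesResult", function(object) {
  if (is.na(object@bf10) || object@bf10 <= 0)
    return("bf10 must be positive")
  TRUE
})

#' Full-comparison report bundle
#'
#' @slot metrics tidy data.frame of single-trial quality metrics (subject,
#'   task, species, method, trial, metric, value).
#' @slot corMats named list of 24 x 24 group correlation matrices, one per
#'   method x species x task cell.
#' @slot corMatTests data.frame of pairwise-method Bayes-factor tests on the
#'   lower-triangular correlation entries.
#' @slot betaMaps named list of per-cell beta-map data.frames (channel,
#'   meanBeta, bf10, n).
#' @slot selections data.frame of per-subject selected channels.
#' @slot config configuration list the bundle was generated from.
#' @slot seeds list of per-stage seeds.
#' @export
setClass("ReportBundle",
  slots = c(metrics = "data.frame", corMats = "list",
            corMatTests = "data.frame", betaMaps = "list",
            selections = "data.frame", config = "list", seeds = "list"))
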