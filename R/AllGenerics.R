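#' @include AllClasses.R
NULL

#' Sampling rate of a signal container
#' @param x a [FnirsSeries-class] object.
#' @return sampling rate in Hz.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname samplingRate
setMethod("samplingRate", "FnirsSeries", function(x) metadata(x)$fs)

#' Probe layout of a signal container
#' @param x a [FnirsSeries-class] object.
#' @return the [ProbeLayout-class].
#' @export
setGeneric("probeLayout", function(x) standardGeneric("probeLayout"))

#' @rdname probeLayout
setMethod("probeLayout", "FnirsSeries", function(x) metadata(x)$layout)

#' Subject age stored with a recording
#' @param x a [FnirsSeries-class] object.
#' @return age in years.
#' @export
setGeneric("subjectAge", function(x) standardGeneric("subjectAge"))

#' @rdname subjectAge
setMethod("subjectAge", "FnirsSeries", function(x) metadata(x)$age)

#' Pruned-channel flags
#' @param x a [FnirsSeries-class] object.
#' @return logical vector, one entry per channel row.
#' @export
setGeneric("prunedChannels", function(x) standardGeneric("prunedChannels"))

#' @rdname prunedChannels
setMethod("prunedChannels", "FnirsSeries", function(x) {
  p <- rowData(x)$pruned
  if (is.null(p)) rep(FALSE, nrow(x)) else as.logical(p)
})

#' Trial onsets of a schedule
#' @param x a [TrialSchedule-class].
#' @param label optional event label filter; by default all task trials
#'   (everything that is not an instruction or break event).
#' @return onset times in seconds.
#' @export
setGeneric("trialOnsets", function(x, label = NULL) standardGeneric("trialOnsets"))

#' @rdname trialOnsets
setMethod("trialOnsets", "TrialSchedule", function(x, label = NULL) {
  ev <- x@events
  if (is.null(label)) ev <- ev[!(ev$label %in% c("instruction", "break")), ]
  else ev <- ev[ev$label == label, ]
  ev$onset
})

#' Corrected series of a correction result
#' @param x a [CorrectionResult-class].
#' @return the corrected [HemoSeries-class].
#' @export
setGeneric("corrected", function(x) standardGeneric("corrected"))

#' @rdname corrected
setMethod("corrected", "CorrectionResult", function(x) x@corrected)

#' Correction method label
#' @param x a [CorrectionResult-class].
#' @return method name.
#' @export
setGeneric("correctionMethod", function(x) standardGeneric("correctionMethod"))

#' @rdname correctionMethod
setMethod("correctionMethod", "CorrectionResult", function(x) x@method)

#' Diagnostics of a correction result
#' @param x a [CorrectionResult-class].
#' @return method-specific diagnostics list.
#' @export
setGeneric("diagnostics", function(x) standardGeneric("diagnostics"))

#' @rdname diagnostics
setMethod("diagnostics", "CorrectionResult", function(x) x@diagnostics)

#' Coefficients of a GLM fit
#' @param object a [GLMFit-class].
#' @param ... unused.
#' @return regressors x series coefficient matrix.
#' @export
setMethod("coef", "GLMFit", function(object, ...) object@betas)

#' Residuals of a GLM fit
#' @param object a [GLMFit-class].
#' @param ... unused.
#' @return samples x series residual matrix (prewhitened scale for AR_IRLS).
#' @export
setMethod("residuals", "GLMFit", function(object, ...) object@residuals)

# ---- show methods -----------------------------------------------------------

setMethod("show", "ProbeLayout", function(object) {
  ch <- object@channels
  cat("ProbeLayout:", sum(ch$type == "regular"), "regular channels (30 mm),",
      sum(ch$type == "sdc"), "SDCs (8 mm) on a", object@headRadius,
      "mm sphere\n")
  reg <- ch[ch$type == "regular", ]
  for (r in unique(reg$roi))
    cat("  ", r, ": channels ", paste(reg$channel[reg$roi == r],
                                      collapse = ", "), "\n", sep = "")
  invisible(NULL)
})

setMethod("show", "TrialSchedule", function(object) {
  tr <- trialOnsets(object)
  cat("TrialSchedule [", object@task, "]: ", length(tr), " trials of ",
      object@taskDuration, " s, onsets ",
      paste(sprintf("%.1f", utils::head(tr, 6)), collapse = ", "),
      if (length(tr) > 6) ", ..." else "", "\n", sep = "")
  invisible(NULL)
})

setMethod("show", "QualityReport", function(object) {
  tb <- object@table
  cat("QualityReport:", sum(tb$pruned), "of", nrow(tb),
      "channels pruned (SCI >=", object@thresholds["sci"], ", PSP >=",
      object@thresholds["psp"], ", Q >=", object@thresholds["q"], ")\n")
  invisible(NULL)
})

setMethod("show", "CorrectionResult", function(object) {
  cat("CorrectionResult [", object@method, "]: ",
      nrow(object@corrected), " channels x ", ncol(object@corrected),
      " samples\n", sep = "")
  invisible(NULL)
})

setMethod("show", "GLMFit", function(object) {
  cat("GLMFit [", object@solver, "]: ", ncol(object@design),
      " regressors, ", ncol(object@betas), " series, AR orders ",
      paste(range(object@arOrders), collapse = "-"), "\n", sep = "")
  invisible(NULL)
})

setMethod("show", "Epochs", function(object) {
  d <- dim(object@hbo)
  cat("Epochs: ", d[1], " trials x ", d[2], " samples x ", d[3],
      " channels, window [", min(object@time), ", ",
      sprintf("%.2f", max(object@time)), "] s\n", sep = "")
  invisible(NULL)
})

setMethod("show", "BayesResult", function(object) {
  cat(sprintf("BayesResult [%s]: BF10 = %.4g (t = %.3f, n = %d, r = %.3f)\n",
              object@mode, object@bf10, object@t, as.integer(object@n),
              object@cauchyScale))
  invisible(NULL)
})

setMethod("show", "ReportBundle", function(object) {
  cat("ReportBundle:", length(object@corMats), "correlation matrices,",
      length(object@betaMaps), "beta maps,", nrow(object@corMatTests),
      "pairwise tests,", nrow(object@metrics), "metric rows\n")
  invisible(NULL)
})
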