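#' @include AllClasses.R glm.R hrf.R
NULL

.ROI_BY_TASK <- c(SIM = "M1_LEFT", ME_LEFT = "M1_RIGHT",
                  ME_RIGHT = "M1_LEFT", MI = "SMA")

#' Epoch a hemoglobin series around trial onsets and baseline-correct
#'
#' Window [-5, 25) s relative to each onset (half-open, onsets snapped to
#' the nearest sample); each epoch is baseline corrected by subtracting the
#' channel mean over the pre-stimulus [-5, 0) s. Trials whose window does
#' not fit inside the recording are dropped.
#'
#' @param hemo a [HemoSeries-class].
#' @param schedule a [TrialSchedule-class].
#' @param label trial label filter passed to [trialOnsets].
#' @param channels row indices to epoch; all rows by default.
#' @param window epoch window in seconds relative to onset.
#' @return an [Epochs-class]; trial order follows the schedule.
#' @export
epochAndBaseline <- function(hemo, schedule, label = NULL, channels = NULL,
                             window = c(-5, 25)) {
  stopifnot(is(hemo, "HemoSeries"))
  fs <- samplingRate(hemo); n <- ncol(hemo)
  if (is.null(channels)) channels <- seq_len(nrow(hemo))
  pre <- round(-window[1] * fs)
  total <- round((window[2] - window[1]) * fs)
  offs <- seq_len(total) - pre - 1L           # 0 = onset sample
  tvec <- offs / fs
  onsets <- trialOnsets(schedule, label)
  keep <- vapply(onsets, function(on) {
    i0 <- round(on * fs) + 1L
    i0 + min(offs) >= 1L && i0 + max(offs) <= n
  }, logical(1))
  onsets <- onsets[keep]
  nT <- length(onsets)
  out <- list()
  for (sp in .SPECIES) {
    M <- assay(hemo, sp)
    arr <- array(NA_real_, c(nT, total, length(channels)))
    for (k in seq_len(nT)) {
      i0 <- round(onsets[k] * fs) + 1L
      seg <- t(M[channels, i0 + offs, drop = FALSE])
      base <- colMeans(seg[tvec < 0, , drop = FALSE])
      arr[k, , ] <- sweep(seg, 2, base)
    }
    out[[sp]] <- arr
  }
  new("Epochs", hbo = out$hbo, hbr = out$hbr, time = tvec, fs = fs,
      channels = as.integer(channels), onsets = onsets)
}

# convolve event sticks/boxcars with the canonical HRF impulse response
.eventRegressor <- function(onsets, durations, n, fs, boxcar = TRUE) {
  x <- numeric(n)
  for (k in seq_along(onsets)) {
    i0 <- round(onsets[k] * fs) + 1L
    if (boxcar) {
      i1 <- min(n, round((onsets[k] + durations[k]) * fs))
      if (i0 <= n) x[i0:i1] <- 1
    } else if (i0 <= n) x[i0] <- 1
  }
  h <- canonicalHRF(fs, 30)
  y <- stats::convolve(x, rev(h), type = "open")[seq_len(n)]
  if (boxcar) y <- y / max(1, sum(h))   # keep boxcar responses near unit scale
  y
}

.withDerivatives <- function(x, fs, name) {
  d1 <- c(0, diff(x)) * fs
  d2 <- c(0, diff(d1)) * fs
  out <- cbind(x, d1, d2)
  colnames(out) <- paste0(name, c("", "_d1", "_d2"))
  out
}

#' Build the task design matrix
#'
#' SIM mode: a single task regressor holding the canonical response to all
#' simulated onsets. REAL mode: one boxcar-convolved canonical regressor
#' per task label plus regressors for the instruction cues and the breaks.
#' Every base regressor is accompanied by its first and second temporal
#' derivatives; an intercept column is appended.
#'
#' @param schedule a [TrialSchedule-class].
#' @param n number of samples.
#' @param fs sampling rate (Hz).
#' @param mode "SIM" or "REAL".
#' @return design matrix (samples x regressors) with named columns.
#' @export
buildTaskDesign <- function(schedule, n, fs, mode = c("SIM", "REAL")) {
  mode <- match.arg(mode)
  ev <- schedule@events
  cols <- list()
  if (mode == "SIM") {
    tr <- ev[!(ev$label %in% c("instruction", "break")), ]
    cols[[1]] <- .withDerivatives(
      .eventRegressor(tr$onset, tr$duration, n, fs, boxcar = FALSE),
      fs, unique(tr$label)[1])
  } else {
    for (lab in setdiff(unique(ev$label), c("instruction", "break"))) {
      sub <- ev[ev$label == lab, ]
      cols[[length(cols) + 1L]] <- .withDerivatives(
        .eventRegressor(sub$onset, sub$duration, n, fs), fs, lab)
    }
    for (lab in c("instruction", "break")) {
      sub <- ev[ev$label == lab, ]
      if (nrow(sub))
        cols[[length(cols) + 1L]] <- .withDerivatives(
          .eventRegressor(sub$onset, sub$duration, n, fs), fs, lab)
    }
  }
  X <- do.call(cbind, cols)
  cbind(X, intercept = 1)
}

#' Task-level GLM over all regular channels
#'
#' Fits the task design ([buildTaskDesign]) to every regular channel of both
#' species with the AR-prewhitened robust solver (or OLS), and collects the
#' task-regressor betas used for channel selection and the group beta maps.
#'
#' @param hemo a corrected [HemoSeries-class].
#' @param schedule the [TrialSchedule-class] of the recording.
#' @param mode "SIM" (single all-onsets regressor) or "REAL".
#' @param solver,maxAROrder passed to [fitGLM].
#' @return a [TaskGLMFit-class].
#' @export
taskGLM <- function(hemo, schedule, mode = c("SIM", "REAL"),
                    solver = c("AR_IRLS", "OLS"),
                    maxAROrder = ceiling(4 * samplingRate(hemo))) {
  mode <- match.arg(mode); solver <- match.arg(solver)
  stopifnot(is(hemo, "HemoSeries"))
  fs <- samplingRate(hemo)
  X <- buildTaskDesign(schedule, ncol(hemo), fs, mode)
  reg <- .rowsOfType(hemo, "regular")
  taskNames <- setdiff(colnames(X), "intercept")
  taskNames <- taskNames[!grepl("_d[12]$", taskNames)]
  taskNames <- setdiff(taskNames, c("instruction", "break"))
  fits <- list(); rows <- list()
  for (sp in .SPECIES) {
    Y <- t(assay(hemo, sp)[reg, , drop = FALSE])
    colnames(Y) <- rownames(hemo)[reg]
    fit <- fitGLM(Y, X, solver = solver, maxAROrder = maxAROrder)
    fits[[sp]] <- fit
    for (tn in taskNames) {
      rows[[length(rows) + 1L]] <- data.frame(
        channel = rowData(hemo)$channel[reg], species = sp, regressor = tn,
        beta = coef(fit)[tn, ], se = fit@se[tn, ],
        t = coef(fit)[tn, ] / fit@se[tn, ], row.names = NULL)
    }
  }
  new("TaskGLMFit", fits = fits, betas = do.call(rbind, rows), mode = mode)
}

#' Select the best channel within the task-specific ROI
#'
#' From a task GLM, picks the regular channel with the highest task beta
#' (oxyhemoglobin) or the lowest (deoxyhemoglobin) among the non-pruned
#' channels of the ROI the task is expected to activate (SIM and ME right:
#' M1 left; ME left: M1 right; MI: SMA). Ties resolve to the lowest channel
#' id.
#'
#' @param fit a [TaskGLMFit-class].
#' @param task task label; also names the regressor in REAL mode.
#' @param layout the [ProbeLayout-class].
#' @param species "hbo" or "hbr".
#' @return the selected regular-channel id.
#' @export
selectBestChannel <- function(fit, task, layout, species = c("hbo", "hbr")) {
  species <- match.arg(species)
  roi <- .ROI_BY_TASK[[task]]
  ch <- layout@channels
  roiIds <- ch$channel[ch$type == "regular" & ch$roi == roi]
  b <- fit@betas
  b <- b[b$species == species & b$regressor == task &
           b$channel %in% roiIds & is.finite(b$beta), ]
  if (!nrow(b)) stop("no usable channel in ROI ", roi)
  key <- if (species == "hbo") -b$beta else b$beta
  b$channel[order(key, b$channel)[1L]]
}
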