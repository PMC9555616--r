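#' @include AllClasses.R simulate.R
NULL

#' Write a raw recording as long-format TSV
#'
#' Columns: channel (layout row name), wavelength (nm), sample_index
#' (1-based), intensity. A sidecar header block of commented key-value
#' lines stores the sampling rate and subject age so the file round-trips.
#'
#' @param rec a [RawRecording-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeRecordingTSV <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# fs\t%.10g", samplingRate(rec)),
               sprintf("# age\t%.10g", subjectAge(rec))), con)
  rows <- list()
  for (wl in names(.WAVELENGTHS)) {
    M <- assay(rec, wl)
    rows[[wl]] <- data.frame(
      channel = rep(rownames(rec), ncol(M)),
      wavelength = .WAVELENGTHS[[wl]],
      sample_index = rep(seq_len(ncol(M)), each = nrow(M)),
      intensity = as.vector(M))
  }
  utils::write.table(do.call(rbind, rows), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a raw recording from the long-format TSV
#'
#' Inverse of [writeRecordingTSV]; the probe layout is reconstructed from
#' [makeProbeLayout] (the layout is fixed, only signals travel in the
#' file).
#'
#' @param path TSV file written by [writeRecordingTSV].
#' @return a [RawRecording-class].
#' @export
readRecordingTSV <- function(path) {
  hdr <- readLines(path, n = 2)
  meta <- lapply(strsplit(sub("^# ", "", hdr), "\t"), function(kv)
    as.numeric(kv[2]))
  names(meta) <- vapply(strsplit(sub("^# ", "", hdr), "\t"), `[`, "", 1)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#")
  layout <- makeProbeLayout()
  chNames <- rownames(layout@channels)
  n <- max(df$sample_index)
  assays <- lapply(.WAVELENGTHS, function(wlnm) {
    sub <- df[df$wavelength == wlnm, ]
    M <- matrix(NA_real_, length(chNames), n,
                dimnames = list(chNames, NULL))
    M[cbind(match(sub$channel, chNames), sub$sample_index)] <- sub$intensity
    M
  })
  names(assays) <- names(.WAVELENGTHS)
  se <- SummarizedExperiment(
    assays = assays,
    rowData = DataFrame(layout@channels, pruned = FALSE),
    metadata = list(fs = meta$fs, layout = layout, age = meta$age))
  rownames(se) <- chNames
  new("RawRecording", se)
}

#' Write a trial schedule as a 3-column TSV (onset, duration, label)
#'
#' @param schedule a [TrialSchedule-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeScheduleTSV <- function(schedule, path) {
  utils::write.table(schedule@events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a trial schedule from a 3-column TSV
#'
#' @param path TSV with columns onset, duration, label.
#' @param task primary task label; inferred from the trial labels when
#'   unique.
#' @return a [TrialSchedule-class].
#' @export
readScheduleTSV <- function(path, task = NULL) {
  ev <- utils::read.table(path, header = TRUE, sep = "\t")
  trialLabs <- setdiff(unique(ev$label), c("instruction", "break"))
  if (is.null(task))
    task <- if (length(trialLabs) == 1L) trialLabs else "SESSION"
  dur <- unique(ev$duration[!(ev$label %in% c("instruction", "break"))])
  new("TrialSchedule", task = task, events = ev,
      taskDuration = dur[1], seed = NA_integer_)
}

#' Write a hemoglobin series as wide CSV
#'
#' One column per channel and species (e.g. \code{R6_hbo}), one row per
#' sample; pruned channels appear as NaN columns.
#'
#' @param hemo a [HemoSeries-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeHemoCSV <- function(hemo, path) {
  out <- data.frame(sample_index = seq_len(ncol(hemo)))
  for (sp in c("hbo", "hbr")) {
    M <- t(assay(hemo, sp))
    colnames(M) <- paste0(rownames(hemo), "_", sp)
    out <- cbind(out, M)
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a quality report as CSV
#'
#' @param report a [QualityReport-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeQualityCSV <- function(report, path) {
  utils::write.csv(report@table, path, row.names = FALSE)
  invisible(path)
}
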