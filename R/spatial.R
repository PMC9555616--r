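#' @include AllClasses.R evaluate.R bayes.R
NULL

#' Channel-SDC correlation matrix of one subject
#'
#' Per trial, the Spearman correlations among 24 concatenated single-trial
#' epochs -- the 16 regular channels taken from the data of the method
#' under evaluation and the 8 SDCs always taken from the uncorrected
#' (NO SAC) data -- averaged over trials ignoring NaN. Pruned channels
#' yield NaN rows/columns. Effective correction shows up as a weakened
#' regular-to-SDC block.
#'
#' @param methodEpochs an [Epochs-class] over all 24 channels of the
#'   corrected series.
#' @param nosacEpochs an [Epochs-class] over all 24 channels of the NO SAC
#'   series (same schedule).
#' @param layout the [ProbeLayout-class].
#' @param species "hbo" or "hbr".
#' @return 24 x 24 symmetric correlation matrix (16 regular then 8 SDC).
#' @export
sdcCorMat <- function(methodEpochs, nosacEpochs, layout,
                      species = c("hbo", "hbr")) {
  species <- match.arg(species)
  a <- if (species == "hbo") methodEpochs@hbo else methodEpochs@hbr
  b <- if (species == "hbo") nosacEpochs@hbo else nosacEpochs@hbr
  ch <- layout@channels
  regIdx <- which(ch$type == "regular")
  sdcIdx <- which(ch$type == "sdc")
  if (length(regIdx) + length(sdcIdx) < 2) stop("need >= 2 channels")
  nT <- dim(a)[1]
  mats <- array(NA_real_, c(nT, 24, 24))
  for (k in seq_len(nT)) {
    X <- cbind(a[k, , regIdx], b[k, , sdcIdx])
    mats[k, , ] <- suppressWarnings(stats::cor(X, method = "spearman"))
  }
  out <- apply(mats, c(2, 3), function(v) mean(v, na.rm = TRUE))
  out[is.nan(out)] <- NaN
  nm <- c(paste0("R", ch$channel[regIdx]), paste0("S", ch$channel[sdcIdx]))
  dimnames(out) <- list(nm, nm)
  out
}

#' Average correlation matrices across subjects, ignoring NaN
#'
#' @param mats list of equally sized matrices.
#' @return element-wise NaN-ignoring mean matrix.
#' @export
averageCorMats <- function(mats) {
  arr <- simplify2array(mats)
  out <- apply(arr, c(1, 2), function(v) mean(v, na.rm = TRUE))
  out[is.nan(out)] <- NaN
  dimnames(out) <- dimnames(mats[[1]])
  out
}

#' Group beta map with per-channel Bayes factors
#'
#' For each of the 16 regular channels the task betas of all subjects are
#' averaged (ignoring NaN from pruned channels) and, where at least
#' \code{minSubjects} subjects contribute, a one-sample
#' Jeffreys-Zellner-Siow Bayes-factor t-test against zero quantifies the
#' group-level activation evidence.
#'
#' @param betasBySubject list of per-subject beta data.frames as produced
#'   by [taskGLM] (columns channel, species, regressor, beta).
#' @param task regressor/task label to extract.
#' @param species "hbo" or "hbr".
#' @param cauchyScale prior scale of the Bayes-factor test.
#' @param minSubjects minimum contributing subjects for a test.
#' @return data.frame with columns channel, meanBeta, bf10, n.
#' @export
betaMap <- function(betasBySubject, task, species = c("hbo", "hbr"),
                    cauchyScale = sqrt(2) / 2, minSubjects = 2L) {
  species <- match.arg(species)
  pull <- function(b) {
    b <- b[b$species == species & b$regressor == task, ]
    stats::setNames(b$beta, b$channel)[as.character(1:16)]
  }
  B <- do.call(rbind, lapply(betasBySubject, pull))   # subjects x 16
  out <- data.frame(channel = 1:16, meanBeta = NA_real_, bf10 = NA_real_,
                    n = 0L)
  for (j in 1:16) {
    v <- B[, j]
    v <- v[is.finite(v)]
    out$n[j] <- length(v)
    if (length(v)) out$meanBeta[j] <- mean(v)
    if (length(v) >= max(3L, minSubjects) && stats::sd(v) > 0)
      out$bf10[j] <- bfTTest(v, mode = "one_sample",
                             cauchyScale = cauchyScale)@bf10
  }
  out
}
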