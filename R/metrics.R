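#' @include AllClasses.R hrf.R
NULL

.minmax <- function(x) {
  r <- range(x)
  if (r[2] == r[1]) return(NULL)
  (x - r[1]) / (r[2] - r[1])
}

# deoxyhemoglobin responds with opposite sign; compare against the flipped
# template so that "higher = better" holds for both species
.signedTemplate <- function(template, species) {
  if (species == "hbr") -template else template
}

#' Scaled root mean square error of a single-trial epoch
#'
#' Epoch and canonical template are min-max scaled to [0, 1], the scaled
#' epoch is regressed on the scaled template (with intercept), and the
#' root-mean-square of the residuals is returned; 0 means the epoch is an
#' affine transform of the template, larger values mean a poorer fit. The
#' deoxyhemoglobin epoch is compared against the sign-flipped template.
#'
#' @param epoch numeric vector (one trial, one channel).
#' @param template canonical HRF evaluated on the same time grid.
#' @param species "hbo" or "hbr".
#' @return sRMSE in [0, 1], or NA for a constant epoch or template.
#' @export
srmse <- function(epoch, template, species = c("hbo", "hbr")) {
  species <- match.arg(species)
  if (anyNA(epoch)) return(NA_real_)
  ys <- .minmax(epoch)
  xs <- .minmax(.signedTemplate(template, species))
  if (is.null(ys) || is.null(xs)) return(NA_real_)
  fit <- stats::lm.fit(cbind(1, xs), ys)
  sqrt(mean(fit$residuals^2))
}

#' Spearman correlation of an epoch with the canonical HRF (Fisher z)
#'
#' Spearman rank correlation between the epoch and the canonical template
#' (sign-flipped for deoxyhemoglobin), clamped to +/-(1 - 1e-7) and
#' Fisher z-transformed (atanh) for averaging and testing.
#'
#' @inheritParams srmse
#' @return Fisher z of Spearman's rho, or NA for constant input.
#' @export
corMeasure <- function(epoch, template, species = c("hbo", "hbr")) {
  species <- match.arg(species)
  if (anyNA(epoch) || stats::sd(epoch) == 0) return(NA_real_)
  tpl <- .signedTemplate(template, species)
  if (stats::sd(tpl) == 0) return(NA_real_)
  rho <- stats::cor(epoch, tpl, method = "spearman")
  atanh(pmin(1 - 1e-7, pmax(-(1 - 1e-7), rho)))
}

#' Single-trial contrast-to-noise ratio
#'
#' The task segment is the epoch within +/-2 s of its peak (maximum for
#' oxy-, minimum for deoxyhemoglobin, searched over the post-onset part of
#' the window and clipped at the epoch edges); the baseline is the
#' pre-stimulus [-5, 0) s. The CNR is
#' \deqn{\frac{\overline{y}_{task} - \overline{y}_{base}}
#'   {\sqrt{var(y_{task}) + var(y_{base})}}}
#' (with \code{rootDenominator = FALSE} the variance sum is left unrooted).
#' The deoxyhemoglobin value is sign-flipped so larger is better for both
#' species.
#'
#' @param epoch numeric vector (one trial, one channel).
#' @param time epoch time axis in seconds (0 = onset).
#' @param species "hbo" or "hbr".
#' @param peakHalfWidth half width of the task segment in seconds.
#' @param rootDenominator take the square root of the pooled variance.
#' @return CNR, or NA when both segments have zero variance.
#' @export
cnr <- function(epoch, time, species = c("hbo", "hbr"), peakHalfWidth = 2,
                rootDenominator = TRUE) {
  species <- match.arg(species)
  if (anyNA(epoch)) return(NA_real_)
  y <- if (species == "hbr") -epoch else epoch
  post <- which(time >= 0)
  ipk <- post[which.max(y[post])]
  task <- y[abs(time - time[ipk]) <= peakHalfWidth]
  base <- y[time < 0]
  v <- stats::var(task) + stats::var(base)
  if (v == 0) return(NA_real_)
  den <- if (rootDenominator) sqrt(v) else v
  (mean(task) - mean(base)) / den
}

#' Per-trial quality metrics of one channel of an Epochs object
#'
#' Convenience wrapper computing sRMSE, Fisher-z Spearman correlation and
#' CNR for every trial of one channel.
#'
#' @param epochs an [Epochs-class].
#' @param channel index into the epoched channel dimension.
#' @param species "hbo" or "hbr".
#' @param template canonical template on the epoch grid; by default the
#'   canonical HRF placed at the onset (zero before it).
#' @return data.frame with columns trial, srmse, cor_fisher_z, cnr.
#' @export
trialMetrics <- function(epochs, channel, species = c("hbo", "hbr"),
                         template = epochTemplate(epochs)) {
  species <- match.arg(species)
  arr <- if (species == "hbo") epochs@hbo else epochs@hbr
  nT <- dim(arr)[1]
  out <- data.frame(trial = seq_len(nT), srmse = NA_real_,
                    cor_fisher_z = NA_real_, cnr = NA_real_)
  for (k in seq_len(nT)) {
    y <- arr[k, , channel]
    out$srmse[k] <- srmse(y, template, species)
    out$cor_fisher_z[k] <- corMeasure(y, template, species)
    out$cnr[k] <- cnr(y, epochs@time, species)
  }
  out
}

#' Canonical template on the grid of an Epochs object
#'
#' Unit-peak canonical HRF starting at onset, zero during the pre-stimulus
#' baseline.
#'
#' @param epochs an [Epochs-class].
#' @return numeric vector matching the epoch sample grid.
#' @export
epochTemplate <- function(epochs) {
  tvec <- epochs@time
  tpl <- numeric(length(tvec))
  post <- tvec >= 0
  h <- canonicalHRF(epochs@fs, max(tvec) + 1 / epochs@fs)
  tpl[post] <- h[seq_len(sum(post))]
  tpl
}
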