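#' @include AllClasses.R probe.R preprocess.R
NULL

.SPECIES <- c("hbo", "hbr")

# usable (non-pruned) row indices among a row subset, judged on the data
.usable <- function(M, rows) rows[apply(M[rows, , drop = FALSE], 1,
                                        function(v) all(is.finite(v)))]

#' Pass-through "correction" (uncorrected reference data)
#'
#' Returns the input unchanged, tagged NO_SAC; serves as the reference
#' condition every correction method is compared against.
#'
#' @param hemo a band-passed [HemoSeries-class].
#' @return a [CorrectionResult-class].
#' @export
correctNone <- function(hemo) {
  new("CorrectionResult", method = "NO_SAC", corrected = hemo,
      diagnostics = list())
}

#' Common average reference correction
#'
#' Per species, the mean time course over all non-pruned regular channels is
#' subtracted from every regular channel:
#' \deqn{x^{CAR}_i = x_i - \frac{1}{N}\sum_{j=1}^{N} x_j.}
#' SDCs are not consulted and pass through uncorrected.
#'
#' @param hemo a band-passed [HemoSeries-class] with >= 2 usable regular
#'   channels.
#' @return a [CorrectionResult-class]; diagnostics hold the subtracted mean
#'   trace per species.
#' @export
correctCAR <- function(hemo) {
  stopifnot(is(hemo, "HemoSeries"))
  reg <- .rowsOfType(hemo, "regular")
  assays <- list(); diag <- list()
  for (sp in .SPECIES) {
    M <- assay(hemo, sp)
    use <- .usable(M, reg)
    if (length(use) < 2) stop("CAR needs >= 2 usable regular channels")
    mu <- colMeans(M[use, , drop = FALSE])
    M[use, ] <- sweep(M[use, , drop = FALSE], 2, mu)
    assays[[sp]] <- M
    diag[[sp]] <- mu
  }
  new("CorrectionResult", method = "CAR",
      corrected = .rebuildSeries(hemo, assays, "HemoSeries"),
      diagnostics = list(meanTrace = diag))
}

#' Gaussian spatial kernel for global component removal
#'
#' Great-circle angular distances D (degrees) between regular-channel
#' midpoints on the layout sphere, mapped through
#' \eqn{G(D) = e^{-D^2 / 2\sigma^2}} and then row-normalised so smoothing
#' preserves scale.
#'
#' @param layout a [ProbeLayout-class].
#' @param sigma kernel width in degrees.
#' @return a [KernelMatrix-class].
#' @examples
#' K <- buildGCRKernel(makeProbeLayout())
#' @export
buildGCRKernel <- function(layout, sigma = 46) {
  D <- channelDistances(layout, "angular", "regular")
  Graw <- exp(-D^2 / (2 * sigma^2))
  G <- Graw / rowSums(Graw)
  new("KernelMatrix", G = G, Graw = Graw, D = D, sigma = sigma)
}

#' Global component removal correction
#'
#' Per species, the non-pruned regular-channel data (samples x channels) are
#' decomposed by SVD, \eqn{Y = U \Sigma V^T}; each spatial singular vector
#' is smoothed by the Gaussian kernel (\eqn{v_i^* = G v_i}), which removes
#' localised patterns so that the reconstruction
#' \eqn{Y_{global} = U \Sigma V^{*T}} holds only the spatially global
#' component; the corrected data are \eqn{Y - Y_{global}}. SDCs are not
#' consulted and pass through.
#'
#' @param hemo a band-passed [HemoSeries-class] with >= 3 usable regular
#'   channels.
#' @param kernel a [KernelMatrix-class] built on the same layout.
#' @return a [CorrectionResult-class]; diagnostics hold the global
#'   component per species.
#' @export
correctGCR <- function(hemo, kernel = buildGCRKernel(probeLayout(hemo))) {
  stopifnot(is(hemo, "HemoSeries"), is(kernel, "KernelMatrix"))
  reg <- .rowsOfType(hemo, "regular")
  assays <- list(); diag <- list()
  for (sp in .SPECIES) {
    M <- assay(hemo, sp)
    use <- .usable(M, reg)
    if (length(use) < 3) stop("GCR needs >= 3 usable regular channels")
    sub <- match(use, reg)                 # kernel indices of usable channels
    G <- kernel@Graw[sub, sub, drop = FALSE]
    G <- G / rowSums(G)                    # renormalise over the survivors
    Y <- t(M[use, , drop = FALSE])         # samples x channels
    sv <- svd(Y)
    Vstar <- G %*% sv$v
    Yglobal <- sv$u %*% (diag(sv$d, length(sv$d)) %*% t(Vstar))
    M[use, ] <- t(Y - Yglobal)
    assays[[sp]] <- M
    diag[[sp]] <- t(Yglobal)
  }
  new("CorrectionResult", method = "GCR",
      corrected = .rebuildSeries(hemo, assays, "HemoSeries"),
      diagnostics = list(globalComponent = diag, sigma = kernel@sigma))
}

#' Short separation regression correction
#'
#' Per species, every regular channel is corrected by its Euclidean-nearest
#' SDC of the same species:
#' \deqn{y^{SSR} = y_{RC} - \alpha\, y_{SDC}, \qquad
#'   \alpha = \frac{\langle y_{SDC}, y_{RC}\rangle}
#'                 {\langle y_{SDC}, y_{SDC}\rangle}.}
#' A pruned nearest SDC falls back to the next-nearest usable one (recorded
#' in the diagnostics); with no usable SDC the method refuses. SDC rows pass
#' through uncorrected.
#'
#' @param hemo a band-passed [HemoSeries-class].
#' @param layout the [ProbeLayout-class]; defaults to the one stored with
#'   the series.
#' @return a [CorrectionResult-class]; diagnostics hold per-channel alpha
#'   and the SDC mapping used.
#' @export
correctSSR <- function(hemo, layout = probeLayout(hemo)) {
  stopifnot(is(hemo, "HemoSeries"))
  reg <- .rowsOfType(hemo, "regular")
  sdcRows <- .rowsOfType(hemo, "sdc")
  sdcIds <- rowData(hemo)$channel[sdcRows]
  assays <- list(); alphas <- list(); maps <- list()
  for (sp in .SPECIES) {
    M <- assay(hemo, sp)
    badSdc <- sdcIds[!(sdcRows %in% .usable(M, sdcRows))]
    if (length(badSdc) == length(sdcIds)) stop("all SDCs pruned")
    mapping <- nearestSDC(layout, exclude = badSdc)
    al <- rep(NA_real_, length(reg))
    for (k in seq_along(reg)) {
      y <- M[reg[k], ]
      if (!all(is.finite(y))) next       # pruned regular channel
      regId <- rowData(hemo)$channel[reg[k]]
      s <- M[sdcRows[match(mapping[[as.character(regId)]], sdcIds)], ]
      # a silent reference channel carries nothing to remove
      a <- if (sum(s * s) == 0) 0 else sum(s * y) / sum(s * s)
      M[reg[k], ] <- y - a * s
      al[k] <- a
    }
    names(al) <- rowData(hemo)$channel[reg]
    assays[[sp]] <- M
    alphas[[sp]] <- al
    maps[[sp]] <- mapping
  }
  new("CorrectionResult", method = "SSR",
      corrected = .rebuildSeries(hemo, assays, "HemoSeries"),
      diagnostics = list(alpha = alphas, sdcMapping = maps))
}
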