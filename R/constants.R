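#' @include AllClasses.R
NULL

# fixed instrument sampling rate (Hz)
.FS <- 7.8125

# partial volume factor of the modified Beer-Lambert law
.PVF <- 1 / 60

# molar extinction coefficients, cm^-1 M^-1, base-10 convention
# (hemoglobin compilation of W.B. Gratzer / N. Kollias as tabulated by
# S. Prahl, https://omlc.org/spectra/hemoglobin/)
.EXTINCTION_BASE10 <- matrix(
  c(586.00, 1548.52,    # 760 nm: HbO2, Hb
    1058.00, 691.32),   # 850 nm: HbO2, Hb
  nrow = 2, byrow = TRUE,
  dimnames = list(c("wl760", "wl850"), c("hbo", "hbr")))

# extinction in cm^-1 per uM for natural-log optical density
.extinctionLn <- function() .EXTINCTION_BASE10 * log(10) * 1e-6

.WAVELENGTHS <- c(wl760 = 760, wl850 = 850)

#' Age- and wavelength-dependent differential pathlength factor
#'
#' General DPF model fitted across published adult head measurements
#' (polynomial in wavelength, power law in age):
#' \deqn{DPF(\lambda, A) = \alpha + \beta A^{\gamma} + \delta \lambda^3 +
#'   \epsilon \lambda^2 + \zeta \lambda}
#' with \eqn{\alpha = 223.3}, \eqn{\beta = 0.05624}, \eqn{\gamma = 0.8493},
#' \eqn{\delta = -5.723\times 10^{-7}}, \eqn{\epsilon = 0.001245},
#' \eqn{\zeta = -0.9025}.
#'
#' @param wavelength wavelength in nm.
#' @param age subject age in years.
#' @return dimensionless DPF.
#' @examples
#' ageDPF(760, 65)
#' @export
ageDPF <- function(wavelength, age) {
  223.3 + 0.05624 * age^0.8493 - 5.723e-7 * wavelength^3 +
    0.001245 * wavelength^2 - 0.9025 * wavelength
}

# partial pathlength factor entering the mBLL: DPF x PVF, PVF = 1/60
.ppf <- function(wavelength, age) ageDPF(wavelength, age) * .PVF

# forward modified Beer-Lambert law: concentration changes (uM) -> optical
# density changes (natural log) for one wavelength. distance in mm.
.forwardOD <- function(hbo, hbr, wl, distanceMM, age) {
  E <- .extinctionLn()
  dcm <- distanceMM / 10
  path <- dcm * .ppf(.WAVELENGTHS[[wl]], age)
  (E[wl, "hbo"] * hbo + E[wl, "hbr"] * hbr) * path
}
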