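#' @include AllClasses.R
NULL

# log of the JZS Bayes factor for a t statistic: Cauchy(0, rscale) prior on
# the standardised effect, integrated via the normal-on-g mixture
# (g ~ InverseGamma(1/2, rscale^2/2)), against the point null
.jzsLogBF10 <- function(t, n, rscale) {
  nu <- n - 1
  logH0 <- -((nu + 1) / 2) * log1p(t^2 / nu)
  logPriorConst <- 0.5 * log(rscale^2 / 2) - lgamma(0.5)
  logIntegrand <- function(u) {           # u = log(g)
    g <- exp(u)
    -0.5 * log1p(n * g) -
      ((nu + 1) / 2) * log1p(t^2 / ((1 + n * g) * nu)) +
      logPriorConst - 1.5 * u - rscale^2 / (2 * g) + u
  }
  # beyond any evidence threshold the integral is numerically degenerate
  if (abs(t) > 1e4) return(Inf)
  us <- seq(-25, 25, length.out = 400)
  off <- max(logIntegrand(us))
  val <- stats::integrate(function(u) {
    v <- logIntegrand(u) - off
    ifelse(is.finite(v), exp(v), 0)
  }, lower = -40, upper = 40, rel.tol = 1e-10,
  subdivisions = 500L)$value
  off + log(val) - logH0
}

#' Jeffreys-Zellner-Siow Bayes-factor t-test
#'
#' One-sample or paired t-test in the Bayesian formulation: the Bayes
#' factor BF10 compares the alternative, a Cauchy prior with scale
#' \code{cauchyScale} on the standardised effect size, against the point
#' null of zero effect, by numerical integration of the marginal
#' likelihood. The default scale sqrt(2)/2 is the conventional "medium"
#' prior.
#'
#' @param x numeric sample (or first member of the pairs).
#' @param y second member of the pairs (paired mode only).
#' @param mode "one_sample" or "paired".
#' @param mu null value of the mean (one-sample) or mean difference.
#' @param cauchyScale Cauchy prior scale.
#' @return a [BayesResult-class].
#' @examples
#' bfTTest(rnorm(24, 1), mode = "one_sample")
#' @export
bfTTest <- function(x, y = NULL, mode = c("one_sample", "paired"), mu = 0,
                    cauchyScale = sqrt(2) / 2) {
  mode <- match.arg(mode)
  if (mode == "paired") {
    if (is.null(y) || length(y) != length(x))
      stop("paired mode needs y of the same length as x")
    x <- x - y
  }
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3) stop("need n >= 3")
  s <- stats::sd(x)
  degenerate <- s == 0
  t <- if (degenerate) {
    if (mean(x) == mu) 0 else Inf
  } else (mean(x) - mu) / (s / sqrt(n))
  logBF <- if (is.infinite(t)) Inf else .jzsLogBF10(t, n, cauchyScale)
  new("BayesResult", bf10 = exp(logBF), logBF10 = logBF, t = t, n = n,
      df = n - 1, cauchyScale = cauchyScale, mode = mode,
      degenerate = degenerate)
}

.EVIDENCE_LABELS <- c("extreme_H0", "very_strong_H0", "strong_H0",
                      "moderate_H0", "anecdotal_H0", "anecdotal_H1",
                      "moderate_H1", "strong_H1", "very_strong_H1",
                      "extreme_H1")

#' Classify a Bayes factor into an evidence category
#'
#' Step-function classification at the thresholds 1/100, 1/30, 1/10, 1/3,
#' 1, 3, 10, 30, 100 (the standard evidence ladder): e.g. BF10 in (3, 10)
#' is moderate evidence for H1, BF10 in (1/10, 1/3) moderate evidence for
#' H0, BF10 > 100 extreme evidence for H1. A Bayes factor exactly on a
#' boundary is assigned to the stronger category.
#'
#' @param bf10 positive Bayes factor(s).
#' @return character vector of category labels (ordered factor levels in
#'   \code{levels}).
#' @export
classifyEvidence <- function(bf10) {
  if (any(!is.na(bf10) & bf10 <= 0)) stop("bf10 must be positive")
  vapply(bf10, function(b) {
    if (is.na(b)) return(NA_character_)
    if (b <= 1 / 100) "extreme_H0"
    else if (b <= 1 / 30) "very_strong_H0"
    else if (b <= 1 / 10) "strong_H0"
    else if (b <= 1 / 3) "moderate_H0"
    else if (b < 1) "anecdotal_H0"
    else if (b < 3) "anecdotal_H1"
    else if (b < 10) "moderate_H1"
    else if (b < 30) "strong_H1"
    else if (b < 100) "very_strong_H1"
    else "extreme_H1"
  }, character(1))
}

#' Pairwise Bayes-factor tests between method correlation matrices
#'
#' For every pair of correction methods, a paired Bayes-factor t-test over
#' the vectorised lower-triangular entries of the two group correlation
#' matrices (NaN pairs dropped listwise). With six methods this yields the
#' 15 pairwise comparisons per task and species.
#'
#' @param mats named list of equally sized correlation matrices, one per
#'   method.
#' @param task,species labels copied into the output.
#' @param cauchyScale prior scale of the paired test.
#' @param minPairs minimum complete entry pairs for a test.
#' @return data.frame: task, species, method1, method2, bf10, logBF10, t,
#'   nPairs, evidence.
#' @export
compareCorMats <- function(mats, task = NA_character_,
                           species = NA_character_,
                           cauchyScale = sqrt(2) / 2, minPairs = 3L) {
  methods <- names(mats)
  lowTri <- lapply(mats, function(M) M[lower.tri(M)])
  pairs <- utils::combn(methods, 2)
  out <- list()
  for (k in seq_len(ncol(pairs))) {
    m1 <- pairs[1, k]; m2 <- pairs[2, k]
    a <- lowTri[[m1]]; b <- lowTri[[m2]]
    ok <- is.finite(a) & is.finite(b)
    row <- data.frame(task = task, species = species, method1 = m1,
                      method2 = m2, bf10 = NA_real_, logBF10 = NA_real_,
                      t = NA_real_, nPairs = sum(ok),
                      evidence = NA_character_)
    if (sum(ok) >= minPairs && stats::sd(a[ok] - b[ok]) >= 0) {
      bf <- bfTTest(a[ok], b[ok], mode = "paired",
                    cauchyScale = cauchyScale)
      row$bf10 <- bf@bf10; row$logBF10 <- bf@logBF10; row$t <- bf@t
      row$evidence <- classifyEvidence(bf@bf10)
    }
    out[[k]] <- row
  }
  do.call(rbind, out)
}
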