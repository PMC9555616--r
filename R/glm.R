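#' @include AllClasses.R correct.R
NULL

# Levinson-Durbin over the sample autocovariance; returns the AR model
# minimising BIC among orders 0..maxOrder
.arSelectBIC <- function(r, maxOrder) {
  n <- length(r)
  maxOrder <- max(0L, min(maxOrder, n - 2L, floor(n / 5)))
  if (maxOrder == 0L) return(list(order = 0L, phi = numeric(0)))
  ac <- stats::acf(r, lag.max = maxOrder, type = "covariance",
                   plot = FALSE, demean = TRUE)$acf[, 1, 1]
  if (ac[1] <= 0) return(list(order = 0L, phi = numeric(0)))
  sigma2 <- ac[1]
  best <- list(order = 0L, phi = numeric(0))
  bestBIC <- n * log(sigma2)
  phi <- numeric(0)
  for (p in seq_len(maxOrder)) {
    k <- if (p == 1) ac[2] / ac[1] else
      (ac[p + 1] - sum(phi * ac[p:2])) / sigma2
    if (!is.finite(k) || abs(k) >= 1) break
    phi <- c(phi - k * rev(phi), k)
    sigma2 <- sigma2 * (1 - k^2)
    bic <- n * log(max(sigma2, 1e-300)) + p * log(n)
    if (bic < bestBIC) {
      bestBIC <- bic
      best <- list(order = p, phi = phi)
    }
  }
  best
}

# apply the AR whitening filter e_t = x_t - sum_j phi_j x_{t-j}; drops the
# first length(phi) rows
.prewhiten <- function(x, phi) {
  p <- length(phi)
  x <- as.matrix(x)
  if (p == 0L) return(x)
  n <- nrow(x)
  out <- x[(p + 1):n, , drop = FALSE]
  for (j in seq_len(p))
    out <- out - phi[j] * x[(p + 1 - j):(n - j), , drop = FALSE]
  out
}

.wls <- function(X, y, w = NULL) {
  if (is.null(w)) {
    fit <- stats::lm.fit(X, y)
  } else {
    sw <- sqrt(w)
    fit <- stats::lm.fit(X * sw, y * sw)
  }
  fit$coefficients
}

#' Fit a general linear model by OLS or AR-prewhitened robust least squares
#'
#' The \code{AR_IRLS} solver iterates: (i) estimate a per-series AR(p) model
#' on the current residuals with the order chosen by BIC up to
#' \code{maxAROrder}; (ii) prewhiten response and design with the AR filter;
#' (iii) refit with Tukey-bisquare robust weights (c = 4.685) on the
#' whitened residuals; until the coefficient change falls below \code{tol}
#' or \code{maxIter} iterations. This yields calibrated standard errors
#' under the serially correlated, spike-prone noise of fNIRS, where plain
#' OLS is anticonservative. All-NaN (pruned) series give NA coefficients.
#'
#' @param Y numeric matrix (samples x series) or vector.
#' @param X design matrix (samples x regressors), full column rank.
#' @param solver "OLS" or "AR_IRLS".
#' @param maxAROrder maximum AR order offered to the BIC selection.
#' @param robust use Tukey-bisquare reweighting in the AR_IRLS solver.
#' @param tol convergence tolerance on max absolute coefficient change.
#' @param maxIter iteration cap of the AR_IRLS loop.
#' @return a [GLMFit-class].
#' @export
fitGLM <- function(Y, X, solver = c("AR_IRLS", "OLS"), maxAROrder = 32L,
                   robust = TRUE, tol = 1e-4, maxIter = 10L) {
  solver <- match.arg(solver)
  Y <- as.matrix(Y); X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("more regressors than samples")
  if (qr(X)$rank < p) stop("rank-deficient design (collinear regressors)")
  nSeries <- ncol(Y)
  betas <- se <- matrix(NA_real_, p, nSeries,
                        dimnames = list(colnames(X), colnames(Y)))
  res <- matrix(NA_real_, n, nSeries)
  arOrders <- integer(nSeries)
  arCoefs <- vector("list", nSeries)
  weights <- vector("list", nSeries)
  dfres <- rep(NA_real_, nSeries)
  XtXinv <- chol2inv(chol(crossprod(X)))
  for (s in seq_len(nSeries)) {
    y <- Y[, s]
    if (!all(is.finite(y))) next
    if (solver == "OLS") {
      b <- .wls(X, y)
      r <- y - X %*% b
      sigma2 <- sum(r^2) / (n - p)
      betas[, s] <- b
      se[, s] <- sqrt(diag(XtXinv) * sigma2)
      res[, s] <- r
      arCoefs[[s]] <- numeric(0)
      dfres[s] <- n - p
      next
    }
    b <- .wls(X, y)
    phi <- numeric(0); w <- NULL; Xw <- X; yw <- y
    for (iter in seq_len(maxIter)) {
      r <- y - X %*% b
      arfit <- .arSelectBIC(as.numeric(r), maxAROrder)
      phi <- arfit$phi
      yw <- as.numeric(.prewhiten(y, phi))
      Xw <- .prewhiten(X, phi)
      rw <- yw - Xw %*% b
      if (robust) {
        sg <- 1.4826 * stats::median(abs(rw - stats::median(rw)))
        if (sg <= 0) sg <- stats::sd(rw)
        u <- rw / (4.685 * sg)
        w <- as.numeric(ifelse(abs(u) < 1, (1 - u^2)^2, 0))
        if (sum(w > 0) <= p) w <- rep(1, length(rw))
      } else w <- rep(1, length(rw))
      bNew <- .wls(Xw, yw, w)
      done <- max(abs(bNew - b)) < tol
      b <- bNew
      if (done) break
    }
    rw <- as.numeric(yw - Xw %*% b)
    sw <- sum(w)
    sigma2 <- sum(w * rw^2) / max(sw - p, 1)
    XtWXinv <- chol2inv(chol(crossprod(Xw * sqrt(w))))
    betas[, s] <- b
    se[, s] <- sqrt(diag(XtWXinv) * sigma2)
    res[, s] <- c(rep(NA_real_, n - length(rw)), rw)
    arOrders[s] <- length(phi)
    arCoefs[[s]] <- phi
    weights[[s]] <- w
    dfres[s] <- sw - p
  }
  new("GLMFit", design = X, betas = betas, se = se, residuals = res,
      arOrders = arOrders, arCoefs = arCoefs, weights = weights,
      solver = solver, df = dfres)
}

#' GLM-based systemic activity correction with SDC regressors
#'
#' The regular channels of both hemoglobin species are regressed on the
#' time courses of the short-distance channels (mean-centred, plus an
#' intercept): all eight SDCs of both species (\code{subset = "ALL"}, 16
#' regressors) or only SDCs 4 and 7, one per hemisphere, of both species
#' (\code{subset = "BH"}, 4 regressors). The corrected data are the part
#' the SDC model cannot explain:
#' \deqn{Y_{corr} = Y - X_{SDC}\hat\beta_{SDC}.}
#' This is the nuisance-only first step of the two-step procedure; the task
#' GLM runs downstream on the corrected series, avoiding task/SDC
#' collinearity. SDC rows pass through uncorrected.
#'
#' @param hemo a band-passed [HemoSeries-class].
#' @param subset "ALL" or "BH".
#' @param solver GLM solver (see [fitGLM]).
#' @param maxAROrder maximum AR order; defaults to about 4 s of lags.
#' @return a [CorrectionResult-class]; diagnostics hold the SDC beta table.
#' @export
correctGLMSDC <- function(hemo, subset = c("ALL", "BH"),
                          solver = c("AR_IRLS", "OLS"),
                          maxAROrder = ceiling(4 * samplingRate(hemo))) {
  subset <- match.arg(subset); solver <- match.arg(solver)
  stopifnot(is(hemo, "HemoSeries"))
  sdcRows <- .rowsOfType(hemo, "sdc")
  sdcIds <- rowData(hemo)$channel[sdcRows]
  wanted <- if (subset == "BH") c(4L, 7L) else sdcIds
  regressors <- list()
  for (sp in .SPECIES) {
    M <- assay(hemo, sp)
    for (id in wanted) {
      v <- M[sdcRows[match(id, sdcIds)], ]
      if (!all(is.finite(v))) {
        if (subset == "BH")
          stop("GLM BH requires SDCs 4 and 7 unpruned; SDC ", id,
               " is pruned")
        next
      }
      if (stats::sd(v) == 0) next   # constant reference carries no signal
      regressors[[paste0("sdc", id, "_", sp)]] <- v - mean(v)
    }
  }
  if (!length(regressors))
    return(new("CorrectionResult", method = paste0("GLM_", subset),
               corrected = hemo,
               diagnostics = list(betaSDC = list(), regressors = character(),
                                  solver = solver,
                                  note = "no informative SDC regressors")))
  Xsdc <- do.call(cbind, regressors)
  X <- cbind(intercept = 1, Xsdc)
  reg <- .rowsOfType(hemo, "regular")
  assays <- list(); betaTabs <- list()
  for (sp in .SPECIES) {
    M <- assay(hemo, sp)
    use <- .usable(M, reg)
    Y <- t(M[use, , drop = FALSE])
    colnames(Y) <- rownames(hemo)[use]
    fit <- fitGLM(Y, X, solver = solver, maxAROrder = maxAROrder)
    bSDC <- coef(fit)[-1, , drop = FALSE]
    M[use, ] <- t(Y - Xsdc %*% bSDC)
    assays[[sp]] <- M
    betaTabs[[sp]] <- bSDC
  }
  new("CorrectionResult", method = paste0("GLM_", subset),
      corrected = .rebuildSeries(hemo, assays, "HemoSeries"),
      diagnostics = list(betaSDC = betaTabs, regressors = colnames(Xsdc),
                         solver = solver))
}
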