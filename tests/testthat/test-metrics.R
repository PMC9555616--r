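tplGrid <- function() {
  tvec <- seq(-5, 25 - 1 / FS, by = 1 / FS)
  tpl <- numeric(length(tvec))
  tpl[tvec >= 0] <- canonicalHRF(FS, 25)[seq_len(sum(tvec >= 0))]
  list(t = tvec, tpl = tpl)
}

test_that("sRMSE is zero for affine fits and matches a regression oracle", {
  g <- tplGrid()
  expect_lt(srmse(3 + 2 * g$tpl, g$tpl, "hbo"), 1e-10)
  # deoxy epochs are compared against the flipped template
  expect_lt(srmse(1 - 0.5 * g$tpl, g$tpl, "hbr"), 1e-10)
  # affine invariance of the min-max scaling
  set.seed(50)
  e <- runif(length(g$tpl))
  expect_equal(srmse(e, g$tpl, "hbo"), srmse(-4 + 7 * e, g$tpl, "hbo"),
               tolerance = 1e-12)
  # independent oracle: explicit lm + RMSE on the scaled variables
  mm <- function(x) (x - min(x)) / (max(x) - min(x))
  fit <- stats::lm(mm(e) ~ mm(g$tpl))
  expect_equal(srmse(e, g$tpl, "hbo"),
               sqrt(mean(stats::residuals(fit)^2)), tolerance = 1e-12)
  expect_true(is.na(srmse(rep(1, length(g$tpl)), g$tpl, "hbo")))
})

test_that("COR is the Fisher z of Spearman's rho with clamping", {
  g <- tplGrid()
  # monotone epoch vs monotone template: rho = 1 pre-clamp
  mono <- seq_along(g$tpl)
  expect_equal(corMeasure(mono, exp(mono / 100), "hbo"), atanh(1 - 1e-7))
  expect_lt(corMeasure(-g$tpl + rnorm(length(g$tpl), sd = 1e-6),
                       g$tpl, "hbo"), 0)
  # brute-force rank oracle
  set.seed(51)
  e <- rnorm(30); tp <- rnorm(30)
  rho <- stats::cor(rank(e), rank(tp))
  expect_equal(corMeasure(e, tp[order(seq_along(tp))], "hbo"),
               atanh(rho), tolerance = 1e-12)
  expect_true(is.na(corMeasure(rep(0, 30), tp, "hbo")))
})

test_that("CNR matches an independent implementation and is scale invariant", {
  g <- tplGrid()
  cnrOracle <- function(y, tvec) {
    post <- which(tvec >= 0)
    pk <- post[which.max(y[post])]
    task <- y[tvec >= tvec[pk] - 2 & tvec <= tvec[pk] + 2]
    base <- y[tvec < 0]
    (mean(task) - mean(base)) / sqrt(stats::var(task) + stats::var(base))
  }
  set.seed(52)
  vals <- vapply(1:200, function(i) {
    y <- g$tpl + rnorm(length(g$tpl), sd = 0.1)
    cnr(y, g$t, "hbo") - cnrOracle(y, g$t)
  }, numeric(1))
  expect_equal(max(abs(vals)), 0, tolerance = 1e-12)
  y <- g$tpl + rnorm(length(g$tpl), sd = 0.1)
  expect_equal(cnr(3 * y, g$t, "hbo"), cnr(y, g$t, "hbo"),
               tolerance = 1e-12)
  # flat epoch: equal means give zero
  z <- rep(c(0.1, -0.1), length.out = length(g$t))
  expect_equal(cnr(z, g$t, "hbo"), 0, tolerance = 0.15)
  # printed (unrooted) variant differs by the root of the variance sum
  v <- cnr(y, g$t, "hbo", rootDenominator = FALSE)
  expect_false(isTRUE(all.equal(v, cnr(y, g$t, "hbo"))))
  # deoxy convention: a negative-going response scores positively
  expect_gt(cnr(-g$tpl, g$t, "hbr"), 0)
})

test_that("metrics degrade monotonically with added noise", {
  g <- tplGrid()
  set.seed(53)
  bySigma <- sapply(c(0.02, 0.2, 1), function(sg) {
    m <- replicate(60, {
      y <- g$tpl + rnorm(length(g$tpl), sd = sg)
      c(srmse(y, g$tpl, "hbo"), corMeasure(y, g$tpl, "hbo"),
        cnr(y, g$t, "hbo"))
    })
    rowMeans(m)
  })
  expect_true(all(diff(bySigma[1, ]) > 0))   # sRMSE grows
  expect_true(all(diff(bySigma[2, ]) < 0))   # COR falls
  expect_true(all(diff(bySigma[3, ]) < 0))   # CNR falls
})
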