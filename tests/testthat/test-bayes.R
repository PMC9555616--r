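test_that("JZS Bayes factors match an independent quadrature oracle", {
  cases <- expand.grid(t = c(0, 0.8, 2.5, 6), n = c(10, 24, 50))
  for (k in seq_len(nrow(cases))) {
    t <- cases$t[k]; n <- cases$n[k]
    mine <- exp(sacnirs:::.jzsLogBF10(t, n, sqrt(2) / 2))
    oracle <- jzsOracle(t, n)
    expect_equal(mine, oracle, tolerance = 1e-4,
                 label = sprintf("BF(t=%g, n=%d)", t, n))
  }
})

test_that("bfTTest honours the t-statistic contract", {
  set.seed(100)
  x <- rnorm(24) + 1
  r <- bfTTest(x, mode = "one_sample")
  expect_equal(r@t, mean(x) / (sd(x) / sqrt(24)), tolerance = 1e-12)
  expect_gt(r@bf10, 1)
  # scale invariance
  expect_equal(bfTTest(10 * x)@bf10, r@bf10, tolerance = 1e-9)
  # paired self-comparison favours the null, degenerate flag set
  p <- bfTTest(x, x, mode = "paired")
  expect_equal(p@t, 0)
  expect_lt(p@bf10, 1)
  expect_true(p@degenerate)
  # strong effect at n = 24
  big <- bfTTest(rnorm(24, mean = 1, sd = 1))
  expect_gt(big@bf10, 100)
  expect_error(bfTTest(c(1, 2)), "n >= 3")
  expect_error(bfTTest(1:5, 1:4, mode = "paired"), "same length")
})

test_that("the Bayes factor is monotone in |t| and calibrated under the null", {
  n <- 20
  bf <- vapply(seq(0, 6, by = 0.5),
               function(t) sacnirs:::.jzsLogBF10(t, n, sqrt(2) / 2),
               numeric(1))
  expect_true(all(diff(bf) > 0))
  set.seed(101)
  nullBF <- vapply(1:100, function(i) bfTTest(rnorm(24))@bf10, numeric(1))
  expect_lt(mean(nullBF > 3), 0.05)
})

test_that("evidence classification follows the standard ladder", {
  expect_equal(classifyEvidence(5), "moderate_H1")
  expect_equal(classifyEvidence(0.2), "moderate_H0")
  expect_equal(classifyEvidence(150), "extreme_H1")
  expect_equal(classifyEvidence(c(0.005, 0.02, 0.2, 0.5, 2, 15, 50)),
               c("extreme_H0", "very_strong_H0", "moderate_H0",
                 "anecdotal_H0", "anecdotal_H1", "strong_H1",
                 "very_strong_H1"))
  # boundaries go to the stronger category
  expect_equal(classifyEvidence(3), "moderate_H1")
  expect_equal(classifyEvidence(1 / 3), "moderate_H0")
  expect_equal(classifyEvidence(100), "extreme_H1")
  expect_error(classifyEvidence(-1), "positive")
  # monotone step function
  bfs <- sort(c(10^seq(-3, 3, length.out = 40)))
  labs <- classifyEvidence(bfs)
  lev <- sacnirs:::.EVIDENCE_LABELS
  expect_true(!is.unsorted(match(labs, lev)))
})

test_that("pairwise correlation-matrix tests cover all 15 method pairs", {
  set.seed(102)
  base <- matrix(runif(24 * 24, -0.2, 0.8), 24)
  base <- (base + t(base)) / 2; diag(base) <- 1
  mats <- lapply(1:6, function(i) base + matrix(rnorm(576, sd = 0.02), 24))
  names(mats) <- c("NO_SAC", "CAR", "GCR", "SSR", "GLM_ALL", "GLM_BH")
  tt <- compareCorMats(mats, task = "SIM", species = "hbo")
  expect_equal(nrow(tt), 15L)
  expect_equal(tt$nPairs, rep(276L, 15))     # 24 * 23 / 2 entries
  # self-comparison favours the null
  self <- compareCorMats(list(A = base, B = base))
  expect_lt(self$bf10[1], 1)
  # a constant 0.2 offset over 276 entries is overwhelming evidence
  off <- compareCorMats(list(A = mats[[1]], B = mats[[1]] + 0.2))
  expect_gt(off$bf10[1], 100)
  # NaN entries are dropped listwise
  m2 <- mats; m2$CAR[3, ] <- NaN; m2$CAR[, 3] <- NaN
  t2 <- compareCorMats(m2)
  expect_lt(min(t2$nPairs), 276L)
})
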