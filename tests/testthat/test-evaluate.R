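test_that("epoching uses the [-5, 25) s grid with exact baseline removal", {
  sched <- makeTrialSchedule("SIM", 5, seed = 7)
  n <- floor(scheduleDuration(sched, 7) * FS)
  hemo <- injectCanonicalHRF(zeroHemo(n), sched, hrfSpec())
  ep <- epochAndBaseline(hemo, sched)
  expect_equal(dim(ep@hbo), c(5L, 234L, 24L))  # round(30 * 7.8125) samples
  expect_equal(sum(ep@time < 0), round(5 * FS))
  base <- apply(ep@hbo[, ep@time < 0, , drop = FALSE], c(1, 3), mean)
  expect_lt(max(abs(base)), 1e-10)
  # trials that do not fit are dropped
  short <- epochAndBaseline(makeHemo(matrix(0, 24, 400),
                                     matrix(0, 24, 400)), sched)
  expect_lt(length(short@onsets), 5L)
})

test_that("SIM task design has one canonical regressor plus derivatives", {
  sched <- makeTrialSchedule("SIM", 5, seed = 7)
  n <- floor(scheduleDuration(sched, 7) * FS)
  X <- buildTaskDesign(sched, n, FS, "SIM")
  expect_equal(ncol(X), 4L)    # task + d1 + d2 + intercept
  expect_true("intercept" %in% colnames(X))
  # the task column equals the sum of onset-shifted canonical templates
  tpl <- canonicalHRF(FS, 30)
  ref <- numeric(n)
  for (on in trialOnsets(sched)) {
    i0 <- round(on * FS) + 1L
    idx <- i0:(i0 + length(tpl) - 1L)
    ref[idx] <- ref[idx] + tpl
  }
  expect_equal(unname(X[, "SIM"]), ref, tolerance = 1e-9)
  # REAL design: 3 tasks + instruction + break, each with 2 derivatives
  sess <- makeSessionSchedule(nTrialsEach = 3, seed = 9)
  Xr <- buildTaskDesign(sess, floor(scheduleDuration(sess, 7) * FS), FS,
                        "REAL")
  expect_equal(ncol(Xr), 16L)
})

test_that("task GLM recovers injection signs and channel selection rules", {
  layout <- makeProbeLayout()
  sched <- makeTrialSchedule("SIM", 5, seed = 7)
  n <- floor(scheduleDuration(sched, 7) * FS)
  set.seed(40)
  hbo <- matrix(rnorm(24 * n, sd = 0.05), 24)
  hbr <- matrix(rnorm(24 * n, sd = 0.05), 24)
  hemo <- injectCanonicalHRF(makeHemo(hbo, hbr), sched, hrfSpec())
  fit <- taskGLM(hemo, sched, "SIM", solver = "OLS")
  b <- fit@betas
  b6 <- b[b$channel == 6, ]
  expect_gt(b6$beta[b6$species == "hbo"], 0)
  expect_lt(b6$beta[b6$species == "hbr"], 0)
  # largest amplitude wins within the ROI; channel 6 before 8
  expect_equal(selectBestChannel(fit, "SIM", layout, "hbo"), 6L)
  expect_equal(selectBestChannel(fit, "SIM", layout, "hbr"), 6L)
  # tie-break towards the lowest channel id
  tie <- fit
  tb <- tie@betas
  tb$beta[tb$species == "hbo"] <- 1
  tie@betas <- tb
  expect_equal(selectBestChannel(tie, "SIM", layout, "hbo"), 5L)
  # a priori ROI assignment per task
  expect_equal(unname(sacnirs:::.ROI_BY_TASK[c("SIM", "ME_LEFT",
                                               "ME_RIGHT", "MI")]),
               c("M1_LEFT", "M1_RIGHT", "M1_LEFT", "SMA"))
})

test_that("null channels rarely show large standardised task betas", {
  sched <- makeTrialSchedule("SIM", 5, seed = 7)
  n <- floor(scheduleDuration(sched, 7) * FS)
  X <- buildTaskDesign(sched, n, FS, "SIM")
  set.seed(41)
  hits <- 0L; total <- 0L
  for (rep in 1:25) {
    y <- rnorm(n)
    fit <- fitGLM(y, X, solver = "OLS")
    tstat <- coef(fit)["SIM", 1] / fit@se["SIM", 1]
    total <- total + 1L
    if (abs(tstat) > 3) hits <- hits + 1L
  }
  expect_lte(hits / total, 0.1)
})
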