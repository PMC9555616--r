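test_that("CAR matches the brute-force mean-subtraction algebra", {
  set.seed(10)
  hbo <- matrix(rnorm(24 * 100), 24)
  hemo <- makeHemo(hbo, matrix(rnorm(24 * 100), 24))
  res <- correctCAR(hemo)
  out <- assay(corrected(res), "hbo")
  # per-sample mean of corrected regular channels is zero
  expect_lt(max(abs(colMeans(out[1:16, ]))), 1e-10)
  # element-wise brute force
  for (i in c(1, 7, 16))
    expect_equal(out[i, ], hbo[i, ] - colMeans(hbo[1:16, ]),
                 tolerance = 1e-12)
  # SDC rows pass through
  expect_equal(out[17:24, ], hbo[17:24, ], ignore_attr = TRUE)
  # identical channels collapse to zero
  same <- makeHemo(matrix(rep(rnorm(100), each = 24), 24))
  expect_lt(max(abs(assay(corrected(correctCAR(same)), "hbo")[1:16, ])),
            1e-12)
  # refuses with fewer than two usable channels
  bad <- hbo; bad[2:16, ] <- NaN
  expect_error(correctCAR(makeHemo(bad)), ">= 2")
})

test_that("CAR and GCR are linear operators for fixed auxiliary inputs", {
  set.seed(11)
  A <- matrix(rnorm(24 * 80), 24); B <- matrix(rnorm(24 * 80), 24)
  K <- buildGCRKernel(makeProbeLayout())
  for (f in list(function(h) correctCAR(h),
                 function(h) correctGCR(h, K))) {
    outA <- assay(corrected(f(makeHemo(A))), "hbo")
    outB <- assay(corrected(f(makeHemo(B))), "hbo")
    outAB <- assay(corrected(f(makeHemo(A + B))), "hbo")
    expect_equal(outAB, outA + outB, tolerance = 1e-6)
  }
})

test_that("GCR kernel follows the Gaussian great-circle definition", {
  K <- buildGCRKernel(makeProbeLayout(), sigma = 46)
  expect_equal(unname(diag(K@Graw)), rep(1, 16))   # e^0 on the diagonal
  expect_equal(K@Graw, t(K@Graw))
  expect_equal(unname(rowSums(K@G)), rep(1, 16))
  # value at D = sigma is exp(-1/2)
  expect_equal(exp(-46^2 / (2 * 46^2)), exp(-0.5))
  i <- which(abs(K@D - 46) == min(abs(K@D - 46)), arr.ind = TRUE)[1, ]
  expect_equal(K@Graw[i[1], i[2]],
               exp(-K@D[i[1], i[2]]^2 / (2 * 46^2)), tolerance = 1e-12)
})

test_that("GCR removes global patterns and respects the SVD identity", {
  set.seed(12)
  layout <- makeProbeLayout()
  K <- buildGCRKernel(layout)
  # spatially uniform pattern: everything is global, output ~ 0
  u <- rnorm(300)
  uni <- makeHemo(matrix(rep(u, each = 24), 24))
  outU <- assay(corrected(correctGCR(uni, K)), "hbo")[1:16, ]
  expect_lt(max(abs(outU)) / stats::sd(u), 1e-6)
  # identity kernel reconstructs the data exactly, so the output is zero
  Kid <- K; Kid@G <- diag(16); Kid@Graw <- diag(16)
  rnd <- makeHemo(matrix(rnorm(24 * 300), 24))
  outI <- assay(corrected(correctGCR(rnd, Kid)), "hbo")[1:16, ]
  expect_lt(max(abs(outI)), 1e-8)
  # SVD reconstruction identity on the raw decomposition
  Y <- t(assay(rnd, "hbo")[1:16, ])
  sv <- svd(Y)
  expect_equal(sv$u %*% diag(sv$d) %*% t(sv$v), Y, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(correctGCR(makeHemo(matrix(NaN, 24, 50)), K), ">= 3")
})

test_that("SSR reproduces the projection algebra with the nearest SDC", {
  set.seed(13)
  layout <- makeProbeLayout()
  hbo <- matrix(rnorm(24 * 50), 24)
  hemo <- makeHemo(hbo)
  res <- correctSSR(hemo, layout)
  out <- assay(corrected(res), "hbo")
  alpha <- diagnostics(res)$alpha$hbo
  mapping <- diagnostics(res)$sdcMapping$hbo
  for (i in c(2, 6, 15)) {
    s <- hbo[16 + mapping[[as.character(i)]], ]
    aRef <- sum(s * hbo[i, ]) / sum(s * s)
    expect_equal(unname(alpha[as.character(i)]), aRef, tolerance = 1e-12)
    # corrected channel orthogonal to its reference SDC
    expect_lt(abs(sum(out[i, ] * s)),
              1e-8 * sqrt(sum(out[i, ]^2) * sum(s^2)))
  }
  # proportional case: alpha recovered exactly, output identically zero
  m6 <- mapping[["6"]]
  prop <- hbo
  prop[6, ] <- 2.5 * hbo[16 + m6, ]
  resP <- correctSSR(makeHemo(prop), layout)
  expect_equal(unname(diagnostics(resP)$alpha$hbo[["6"]]), 2.5,
               tolerance = 1e-12)
  expect_lt(max(abs(assay(corrected(resP), "hbo")[6, ])), 1e-10)
  # pruned nearest SDC falls back to the next-nearest
  pr <- hbo; pr[16 + m6, ] <- NaN
  resF <- correctSSR(makeHemo(pr), layout)
  expect_false(diagnostics(resF)$sdcMapping$hbo[["6"]] == m6)
  expect_true(all(is.finite(assay(corrected(resF), "hbo")[6, ])))
})

test_that("GLM-based correction annihilates exact SDC combinations", {
  set.seed(14)
  hbo <- matrix(rnorm(24 * 200), 24)
  hbr <- matrix(rnorm(24 * 200), 24)
  # regular channels as exact linear combinations of SDC time courses
  W <- matrix(rnorm(16 * 16), 16)
  S <- rbind(hbo[17:24, ], hbr[17:24, ])
  Sc <- S - rowMeans(S)
  hbo[1:16, ] <- W %*% Sc + 2     # constant offset absorbed by intercept
  hemo <- makeHemo(hbo, hbr)
  res <- correctGLMSDC(hemo, "ALL", solver = "OLS")
  out <- assay(corrected(res), "hbo")[1:16, ]
  out <- out - rowMeans(out)
  expect_lt(max(abs(out)) / stats::sd(hbo[1:16, ]), 1e-8)
  # BH uses exactly SDCs 4 and 7 of both species
  resBH <- correctGLMSDC(hemo, "BH", solver = "OLS")
  expect_setequal(diagnostics(resBH)$regressors,
                  c("sdc4_hbo", "sdc7_hbo", "sdc4_hbr", "sdc7_hbr"))
  # refuses when SDC 4 is pruned
  bad <- assay(hemo, "hbo"); bad[16 + 4, ] <- NaN
  expect_error(correctGLMSDC(makeHemo(bad, hbr), "BH", solver = "OLS"),
               "SDC 4")
})

test_that("SDC-based methods return the injected HRF unchanged without SA", {
  layout <- makeProbeLayout()
  sched <- makeTrialSchedule("SIM", 5, seed = 21)
  n <- floor(scheduleDuration(sched, 7) * FS)
  # silent background: the SDCs carry nothing, so SDC-based corrections
  # must leave the injected response untouched
  hemo <- injectCanonicalHRF(zeroHemo(n), sched, hrfSpec())
  bp <- bandpassHemo(hemo)
  ref <- assay(bp, "hbo")[6, ]
  for (res in list(correctSSR(bp, layout),
                   correctGLMSDC(bp, "ALL", solver = "OLS"),
                   correctGLMSDC(bp, "BH", solver = "OLS"))) {
    out <- assay(corrected(res), "hbo")[6, ]
    expect_lt(max(abs(out - ref)) / max(ref), 0.02)
  }
})

test_that("methods respect the information-boundary contract", {
  # CAR/GCR ignore SDC rows entirely; SSR/GLM ignore other regular channels
  set.seed(23)
  layout <- makeProbeLayout()
  A <- matrix(rnorm(24 * 120), 24)
  B <- A; B[17:24, ] <- rnorm(8 * 120)    # perturb only SDCs
  K <- buildGCRKernel(layout)
  expect_equal(assay(corrected(correctCAR(makeHemo(A))), "hbo")[1:16, ],
               assay(corrected(correctCAR(makeHemo(B))), "hbo")[1:16, ])
  expect_equal(assay(corrected(correctGCR(makeHemo(A), K)), "hbo")[1:16, ],
               assay(corrected(correctGCR(makeHemo(B), K)), "hbo")[1:16, ])
  C <- A; C[2:16, ] <- rnorm(15 * 120)    # perturb other regular channels
  s1 <- assay(corrected(correctSSR(makeHemo(A), layout)), "hbo")[1, ]
  s2 <- assay(corrected(correctSSR(makeHemo(C), layout)), "hbo")[1, ]
  expect_equal(s1, s2)
})
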