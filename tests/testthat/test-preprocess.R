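test_that("optical density conversion follows the log-ratio contract", {
  layout <- makeProbeLayout()
  rec <- simulateRestRecording(layout, 60, saParams(), 65, seed = 2)
  od <- intensityToOD(rec)
  # constant channel gives all-zero OD
  recC <- simulateRestRecording(layout, 60, silentParams(), 65, seed = 2)
  odC <- intensityToOD(recC)
  expect_equal(max(abs(assay(odC, "wl760"))), 0)
  # scale invariance: doubling intensity leaves OD untouched
  rec2 <- rec
  assay(rec2, "wl760") <- assay(rec, "wl760") * 3.7
  expect_equal(assay(intensityToOD(rec2), "wl760"), assay(od, "wl760"),
               tolerance = 1e-12)
  # hand value: one sample at half the (otherwise constant) reference
  I <- assay(recC, "wl760")
  n <- ncol(I)
  I[1, 10] <- I[1, 10] / 2
  assay(recC, "wl760") <- I
  odH <- assay(intensityToOD(recC), "wl760")
  ref <- I[1, 1] * (n - 0.5) / n     # mean after halving one sample
  expect_equal(unname(odH[1, 10]), unname(-log((I[1, 1] / 2) / ref)),
               tolerance = 1e-12)
  expect_equal(unname(odH[1, 10]), log(2), tolerance = 5e-3)
})

test_that("TDDR repairs step artifacts while roughly preserving smooth signal", {
  fs <- FS
  t <- (0:1599) / fs
  y <- sin(2 * pi * 0.1 * t)
  # smooth signal approximately preserved away from the edges
  yc <- sacnirs:::.tddr1(y, fs)
  expect_length(yc, length(y))
  expect_lt(max(abs(yc - y)[100:1500]), 0.15)
  # near-idempotence on the already-repaired signal
  ycc <- sacnirs:::.tddr1(yc, fs)
  expect_lt(max(abs(ycc - yc)[100:1500]), 0.1)
  # a baseline jump (motion artifact) is strongly suppressed
  y2 <- y; y2[801:1600] <- y2[801:1600] + 3
  y2c <- sacnirs:::.tddr1(y2, fs)
  jump <- (mean(y2c[810:900]) - mean(y2c[700:790])) -
    (mean(y[810:900]) - mean(y[700:790]))
  expect_lt(abs(jump) / 3, 0.2)
  # degenerate input passes through
  expect_identical(sacnirs:::.tddr1(rep(2, 100), fs), rep(2, 100))
})

test_that("mBLL inverts its forward model and honours PPF = DPF/60", {
  layout <- makeProbeLayout()
  n <- 200
  hbo <- matrix(rep(sin(2 * pi * 0.05 * (0:(n - 1)) / FS), each = 24),
                24) * 1                       # 1 uM amplitude
  hbr <- -0.3 * hbo                           # (1, -0.3) uM pattern
  # exact round trip at the optical-density level
  odAssays <- lapply(c(wl760 = "wl760", wl850 = "wl850"), function(wl)
    sacnirs:::.forwardOD(hbo, hbr, wl, layout@channels$distance, 65))
  rec0 <- simulateRestRecording(layout, 40, silentParams(), 65, 1)
  od <- sacnirs:::.rebuildSeries(intensityToOD(rec0)[, 1:200], odAssays,
                                 "ODSeries")
  hemo <- odToHemoglobin(od, age = 65)
  expect_equal(assay(hemo, "hbo"), hbo, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(assay(hemo, "hbr"), hbr, tolerance = 1e-9,
               ignore_attr = TRUE)
  # the intensity path recovers the same signal up to a per-channel offset
  # (the reference intensity is the temporal mean, not the baseline)
  rec <- sacnirs:::.concToRecording(hbo, hbr, layout, 65, saParams())
  hemoI <- odToHemoglobin(intensityToOD(rec))
  got <- assay(hemoI, "hbo")
  expect_equal(got - rowMeans(got), hbo - rowMeans(hbo), tolerance = 1e-9,
               ignore_attr = TRUE)
  # all-zero OD maps to all-zero concentrations
  recC <- simulateRestRecording(layout, 60, silentParams(), 65, 1)
  hemoC <- odToHemoglobin(intensityToOD(recC))
  expect_equal(max(abs(assay(hemoC, "hbo"))), 0)
  # pathlength scaling: doubling PPF would halve concentrations; check the
  # embedded constants directly
  expect_equal(sacnirs:::.PVF, 1 / 60)
  expect_equal(sacnirs:::.ppf(760, 65), ageDPF(760, 65) / 60)
  expect_gt(ageDPF(850, 80), ageDPF(850, 30))  # DPF grows with age
})

test_that("band-pass is zero-phase with the contracted gain profile", {
  n <- 8000
  tt <- (0:(n - 1)) / FS
  mk <- function(f) makeHemo(matrix(rep(sin(2 * pi * f * tt), each = 24), 24))
  mid <- 2000:6000
  # DC rejected
  bpC <- bandpassHemo(makeHemo(matrix(1, 24, n)))
  expect_lt(max(abs(assay(bpC, "hbo")[1, mid])), 1e-5)
  # passband gain near unity at 0.05 Hz
  g05 <- max(assay(bandpassHemo(mk(0.05)), "hbo")[1, mid])
  expect_gte(g05, 0.9); expect_lte(g05, 1.0)
  # cardiac frequency crushed
  g11 <- max(abs(assay(bandpassHemo(mk(1.1)), "hbo")[1, mid]))
  expect_lt(g11, 0.01)
  # zero phase: cross-correlation peak at zero lag for in-band signal
  x <- sin(2 * pi * 0.05 * tt)
  y <- assay(bandpassHemo(mk(0.05)), "hbo")[1, ]
  cc <- stats::ccf(x[mid], y[mid], lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  expect_error(bandpassHemo(mk(0.05), low = 0.5, high = 0.1), "low < high")
})

test_that("pruned channels propagate as NaN through the chain", {
  layout <- makeProbeLayout()
  rec <- simulateRestRecording(layout, 60, saParams(), 65, seed = 3)
  qr <- assessChannelQuality(rec)
  qr@table$pruned[qr@table$channel == 3 & qr@table$type == "regular"] <- TRUE
  od <- pruneChannels(intensityToOD(rec), qr)
  expect_true(all(is.nan(assay(od, "wl760")[3, ])))
  expect_true(prunedChannels(od)[3])
  hemo <- bandpassHemo(odToHemoglobin(tddr(od)))
  expect_true(all(is.nan(assay(hemo, "hbo")[3, ])))
  expect_true(all(is.finite(assay(hemo, "hbo")[4, ])))
})
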