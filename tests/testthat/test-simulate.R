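test_that("trial schedules respect the blocked-design timing contract", {
  s <- makeTrialSchedule("SIM", 5, seed = 7)
  on <- trialOnsets(s)
  expect_length(on, 5L)
  expect_gte(on[1], 5)
  gaps <- diff(on) - 15
  expect_true(all(gaps >= 18 & gaps <= 22))
  # seed determinism and boundary case
  expect_identical(s@events, makeTrialSchedule("SIM", 5, seed = 7)@events)
  s1 <- makeTrialSchedule("SIM", 1, seed = 0)
  expect_gte(trialOnsets(s1)[1], 5)
  expect_error(makeTrialSchedule("SIM", 0, seed = 1), "nTrials")
})

test_that("session schedules interleave tasks with cues and breaks", {
  s <- makeSessionSchedule(nTrialsEach = 5, seed = 3)
  ev <- s@events
  expect_equal(sum(ev$label == "ME_LEFT"), 5L)
  expect_equal(sum(ev$label == "ME_RIGHT"), 5L)
  expect_equal(sum(ev$label == "MI"), 5L)
  expect_equal(sum(ev$label == "instruction"), 15L)
  expect_gte(sum(ev$label == "break"), 1L)
  expect_false(is.unsorted(ev$onset))
  tr <- ev[!(ev$label %in% c("instruction", "break")), ]
  expect_true(all(diff(tr$onset) - 15 >= 18 - 1e-9))
})

test_that("rest recordings have the contracted shape and determinism", {
  layout <- makeProbeLayout()
  rec <- simulateRestRecording(layout, 180, saParams(), 65, seed = 1)
  expect_s4_class(rec, "RawRecording")
  expect_equal(dim(rec), c(24L, 1406L))   # floor(180 * 7.8125)
  expect_equal(samplingRate(rec), 7.8125)
  for (a in c("wl760", "wl850"))
    expect_true(all(assay(rec, a) > 0))
  rec2 <- simulateRestRecording(layout, 180, saParams(), 65, seed = 1)
  expect_identical(assay(rec, "wl760"), assay(rec2, "wl760"))
  rec3 <- simulateRestRecording(layout, 180, saParams(), 65, seed = 2)
  expect_false(identical(assay(rec, "wl760"), assay(rec3, "wl760")))
  expect_error(simulateRestRecording(layout, 10, saParams(), 65, 1),
               "duration")
})

test_that("silent parameters produce constant intensities", {
  rec <- simulateRestRecording(makeProbeLayout(), 60, silentParams(), 65, 1)
  for (a in c("wl760", "wl850"))
    expect_equal(max(apply(assay(rec, a), 1, stats::sd)), 0)
})

test_that("systemic-activity coherence decays with inter-channel distance", {
  layout <- makeProbeLayout()
  rec <- simulateRestRecording(layout, 600, saParams(), 65, seed = 11)
  hemo <- odToHemoglobin(intensityToOD(rec))
  # isolate the Mayer-band neighbourhood and correlate channel pairs
  bf <- signal::butter(3, c(0.05, 0.15) / (7.8125 / 2), type = "pass")
  M <- t(apply(assay(hemo, "hbo"), 1, function(y) signal::filtfilt(bf, y)))
  C <- stats::cor(t(M))
  D <- channelDistances(layout, "euclidean", "all")
  lt <- lower.tri(D)
  fit <- stats::lm(C[lt] ~ D[lt])
  expect_lt(stats::coef(fit)[2], 0)
  # monotone non-increasing in rank terms as well
  expect_lt(stats::cor(C[lt], D[lt], method = "spearman"), -0.2)
})

test_that("task-evoked systemic activity is onset-locked and optional", {
  layout <- makeProbeLayout()
  sched <- makeTrialSchedule("SIM", 5, seed = 5)
  p0 <- saParams()
  rec <- simulateRestRecording(layout, scheduleDuration(sched, 7), p0, 65,
                               seed = 9)
  expect_identical(addTaskEvokedSA(rec, sched, p0, seed = 1), rec)
  pTask <- saParams(taskEvokedRegular = 3, taskEvokedSdc = 3)
  recT <- addTaskEvokedSA(rec, sched, pTask, seed = 1)
  expect_false(identical(assay(recT, "wl760"), assay(rec, "wl760")))
  recT2 <- addTaskEvokedSA(rec, sched, pTask, seed = 1)
  expect_identical(assay(recT, "wl760"), assay(recT2, "wl760"))
  # SDC trial averages rise above baseline after conversion to hemoglobin
  hemo <- odToHemoglobin(intensityToOD(recT))
  ep <- epochAndBaseline(hemo, sched, channels = 17:24)
  taskMean <- mean(ep@hbo[, ep@time >= 2 & ep@time <= 12, ])
  baseMean <- mean(ep@hbo[, ep@time < 0, ])
  expect_gt(taskMean, baseMean)
})
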