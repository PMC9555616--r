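suppressMessages({
  library(SummarizedExperiment)
  library(S4Vectors)
})

FS <- 7.8125

# HemoSeries built directly from hbo/hbr matrices (24 rows, layout order)
makeHemo <- function(hbo, hbr = -hbo / 3, layout = makeProbeLayout(),
                     fs = FS, age = 65) {
  se <- SummarizedExperiment(
    assays = list(hbo = hbo, hbr = hbr),
    rowData = DataFrame(layout@channels, pruned = FALSE),
    metadata = list(fs = fs, layout = layout, age = age))
  rownames(se) <- rownames(layout@channels)
  new("HemoSeries", se)
}

# all-zero HemoSeries of n samples
zeroHemo <- function(n, layout = makeProbeLayout()) {
  makeHemo(matrix(0, 24, n), matrix(0, 24, n), layout)
}

# a silent recording: no systemic activity, no noise
silentParams <- function() {
  p <- saParams()
  p@components$amplitude[] <- 0
  p@noiseSD <- 0
  p
}

# a fully processed semisimulated subject (SIM session); returns the
# band-passed HemoSeries, schedule and layout
simSubject <- function(seedSched, seedRec, params = saParams(),
                       layout = makeProbeLayout(), inject = TRUE,
                       prune = FALSE) {
  sched <- makeTrialSchedule("SIM", 5, seed = seedSched)
  rec <- simulateRestRecording(layout, scheduleDuration(sched, 7), params,
                               age = 65, seed = seedRec)
  od <- intensityToOD(rec)
  if (prune) od <- pruneChannels(od, assessChannelQuality(rec))
  hemo <- odToHemoglobin(tddr(od))
  if (inject) hemo <- injectCanonicalHRF(hemo, sched, hrfSpec())
  list(hemo = bandpassHemo(hemo), schedule = sched, layout = layout)
}

# independent quadrature oracle for the JZS Bayes factor: Simpson's rule on
# the substitution g = q / (1 - q), q in (0, 1)
jzsOracle <- function(t, n, rscale = sqrt(2) / 2, nGrid = 20001) {
  nu <- n - 1
  q <- seq(1e-9, 1 - 1e-9, length.out = nGrid)
  g <- q / (1 - q)
  jac <- 1 / (1 - q)^2
  dens <- (rscale^2 / 2)^(1 / 2) / gamma(1 / 2) * g^(-3 / 2) *
    exp(-rscale^2 / (2 * g))
  f <- (1 + n * g)^(-1 / 2) *
    (1 + t^2 / ((1 + n * g) * nu))^(-(nu + 1) / 2) * dens * jac
  h <- q[2] - q[1]
  w <- rep(c(4, 2), length.out = nGrid - 2)
  integral <- h / 3 * (f[1] + sum(w * f[2:(nGrid - 1)]) + f[nGrid])
  integral / (1 + t^2 / nu)^(-(nu + 1) / 2)
}
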