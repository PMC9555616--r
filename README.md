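# sacnirs

Systemic activity contaminates functional near-infrared spectroscopy
(fNIRS): blood-pressure (Mayer) waves, respiration, cardiac pulsation and
slow scalp blood-flow oscillations appear in every channel and can mimic or
mask the cortical hemodynamic response. **sacnirs** is an R package for
*evaluating* systemic-activity correction (SAC) methods on a motor-cortex
montage with short-distance channels (SDCs). It is aimed at fNIRS
methodologists and neurofeedback/BCI developers who need a controlled,
fully synthetic test bed: every recording is generated with known ground
truth, so the gain (or damage) of each correction can be measured exactly.

## What it implements

**Synthetic cohort.** Dual-wavelength (760/850 nm) intensity recordings at
7.8125 Hz on a fixed layout of 16 regular channels (30 mm) in three ROIs
(M1 left, M1 right, SMA) plus 8 SDCs (8 mm). The interference model is a
sum of narrow-band oscillators (very-low-frequency, Mayer, respiratory,
cardiac) shared across the scalp with spatially decaying coherence, 1/f
channel noise, and an optional task-locked systemic waveform; it is pushed
through the forward modified Beer–Lambert law so that preprocessing
inverts it exactly up to noise.

**Preprocessing.** Channel quality control via the scalp coupling index
and peak spectral power (SCI ≥ 0.6, PSP ≥ 0.1, Q ≥ 0.65); optical-density
conversion; temporal derivative distribution repair (TDDR) for motion
artifacts; the modified Beer–Lambert law with the age-dependent DPF and
PPF = DPF × 1/60; canonical-HRF injection (peak at 6 s; 10 µM into channel
6 and 5 µM into channel 8 for Δ[HbO], −1/3 of that for Δ[HbR]) to create
semisimulated task data; zero-phase Butterworth band-pass 0.01–0.09 Hz.

**Corrections.** Five methods plus the uncorrected reference (NO SAC):

- CAR — common average reference,
  `x_i^CAR = x_i − (1/N) Σ_j x_j`;
- GCR — global component removal: SVD `Y = UΣVᵀ`, spatial vectors smoothed
  by the Gaussian kernel `G(D) = exp(−D²/2σ²)` (σ = 46°, great-circle
  distance), global part `Y_global = UΣV*ᵀ` subtracted;
- SSR — short separation regression against the Euclidean-nearest SDC,
  `y^SSR = y_RC − α y_SDC`, `α = ⟨y_SDC, y_RC⟩ / ⟨y_SDC, y_SDC⟩`;
- GLM ALL — residual of a GLM with all 8 SDCs of both species as
  regressors, `Y_corr = Y − X_SDC β_SDC`;
- GLM BH — same with only SDCs 4 and 7 (one per hemisphere).

The GLM solver is AR-IRLS: per-channel AR(p) prewhitening (p by BIC, up to
≈4 s of lags) with Tukey-bisquare robust reweighting, which keeps
standard errors calibrated under serially correlated, spike-prone noise.

**Evaluation.** Single-trial epochs ([−5, 25) s, baseline-corrected) of
the best ROI channel (largest |task beta| from the GLM ALL fit) are scored
by scaled RMSE against the min–max-scaled canonical HRF, Fisher-z Spearman
correlation, and contrast-to-noise ratio (peak ± 2 s vs. baseline).
Spatial specificity: 24 × 24 channel–SDC Spearman correlation matrices and
group beta maps with per-channel one-sample Bayes factors. Method
contrasts use Jeffreys–Zellner–Siow Bayes-factor t-tests (Cauchy prior,
scale √2/2) with the standard evidence ladder (BF10 > 3 moderate, > 10
strong, > 100 extreme, …).

## Worked example

```r
library(sacnirs)
layout <- makeProbeLayout()
sched  <- makeTrialSchedule("SIM", 5, seed = 7)
rec    <- simulateRestRecording(layout, scheduleDuration(sched, 7),
                                saParams(), age = 65, seed = 1)
hemo   <- injectCanonicalHRF(odToHemoglobin(tddr(intensityToOD(rec))),
                             sched, hrfSpec())
bp     <- bandpassHemo(hemo)

glmAll <- correctGLMSDC(bp, "ALL")
fit    <- taskGLM(corrected(glmAll), sched, "SIM")
selectBestChannel(fit, "SIM", layout, "hbo")
#> [1] 6

epCorr <- epochAndBaseline(corrected(glmAll), sched)
epRaw  <- epochAndBaseline(bp, sched)
rbind(GLM_ALL = colMeans(trialMetrics(epCorr, 6, "hbo")[-1]),
      NO_SAC  = colMeans(trialMetrics(epRaw,  6, "hbo")[-1]))
#>             srmse cor_fisher_z       cnr
#> GLM_ALL 0.1142700    1.5692831 11.006124
#> NO_SAC  0.2322492    0.5698753  6.254246

bfTTest(trialMetrics(epCorr, 6, "hbo")$cor_fisher_z,
        trialMetrics(epRaw,  6, "hbo")$cor_fisher_z, mode = "paired")
#> BayesResult [paired]: BF10 = 7.452 (t = 4.707, n = 5, r = 0.707)
```

The channel carrying the 10 µM injection (channel 6) is recovered as the
best ROI channel; correcting with the all-SDC GLM roughly halves the
single-trial scaled RMSE, triples the HRF correlation and nearly doubles
the contrast-to-noise ratio relative to the uncorrected data, and the
paired Bayes factor rates this improvement as moderate evidence even from
five trials.

`runFullComparison(reportConfig(nSubjects = 6, seed = 1))` runs the whole
grid — two sessions per subject (semisimulated and multi-task), six
methods, task GLMs, channel selection, metrics, 48 correlation matrices,
48 beta maps and 120 pairwise Bayes-factor tests — into a single
`ReportBundle`.

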