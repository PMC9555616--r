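---
title: "Evaluating systemic-activity correction for fNIRS: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating systemic-activity correction for fNIRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

fNIRS channels at ~30 mm source–detector separation sample a mixture of
cortical hemodynamics and extracerebral physiology: Mayer waves near
0.1 Hz, respiration near 0.25 Hz, cardiac pulsation above 1 Hz, and slow
scalp blood-flow oscillations well inside the 0.01–0.09 Hz band where the
task response lives. Short-distance channels (SDCs, ~8 mm) sample mostly
the extracerebral layer and therefore act as nuisance references. This
package provides a complete, synthetic-data-driven test bed for comparing
five correction strategies — two spatial filters that need no SDCs (common
average reference, CAR; global component removal, GCR) and three
SDC-based regressions (short separation regression, SSR; GLM with all
SDCs, GLM ALL; GLM with one SDC per hemisphere, GLM BH) — against the
uncorrected reference (NO SAC).

Because the real recordings such comparisons are usually run on cannot be
shipped, everything here operates on a generative model with known ground
truth. That is a strength (signal recovery can be measured exactly) and a
limitation (conclusions transfer to real data only insofar as the model
captures the relevant physiology); both sides are spelled out below.

## Signal model of the synthetic cohort

`simulateRestRecording()` builds the hemodynamic layer in concentration
units (µM) and converts it to raw dual-wavelength intensity through the
forward modified Beer–Lambert law (mBLL), so the preprocessing chain
inverts it exactly up to noise.

The systemic layer is a sum over frequency bands. Each band contributes
one or more *sources*:

\[ s_i(t) = \frac{A}{\sqrt{K}}\, w_i \cos\big(2\pi f t + \phi_0 +
   \delta(t) + \psi_i\big) \]

where \(\delta(t)\) is a phase-diffusion term giving the band its
linewidth, and \(w_i\) (amplitude weights) and \(\psi_i\) (phase offsets)
are Gaussian-process draws over channel positions with covariance
\(\exp(-d^2/2\ell^2)\). Coherence between two channels therefore decays
with their distance — nearby channels (and an SDC next to a channel) see
nearly the same oscillation, distant ones progressively decorrelate.

Default parameters, chosen once on physiological grounds:

| parameter | default | rationale |
|---|---|---|
| bands (Hz / µM) | vlf 0.04 / 7; Mayer 0.10 / 5; resp. 0.25 / 2; cardiac 1.10 / 1 | slow scalp oscillations and Mayer waves dominate the analysis band; respiration and pulse are needed for realistic quality-control behaviour |
| sources per band | 3, 2, 1, 1 | low-frequency scalp flow is not a single global oscillator; distinct vascular territories fluctuate semi-independently |
| spatial scale \(\ell\) | 45 mm | coherence patch of a vascular territory, a few centimetres |
| phase jitter | 2.0 rad | strong spatial heterogeneity of the systemic field |
| amplitude jitter | 0.4 | idem |
| 1/f noise | 0.5 µM, ×2 on SDCs | short channels pick up idiosyncratic superficial vasculature that long channels average out |
| HbR layer | 0.4 × HbO, lagged 0.9 rad | deoxyhemoglobin oscillations trail oxyhemoglobin (venous transit) |
| subject age | 65 y | enters the DPF; cohort of older adults |

Task-evoked systemic activity (a gamma-shaped waveform time-locked to
onsets, added to regular channels and/or SDCs) is available via
`addTaskEvokedSA()` but disabled by default: the semisimulated sessions
deliberately contain no systemic task confound, so any task-locked signal
outside the injected channels is a correction artifact.

What the generator does **not** emulate: photon transport and partial
optical pathlengths per layer (the mBLL forward model is used with the
same coefficients the inversion uses, so conversion errors cancel by
construction), motion artifacts other than what TDDR-style tests inject
explicitly, inhomogeneous optode coupling, and genuinely cortical resting
oscillations. Passing tests therefore demonstrate the *relative* behaviour
of the corrections under a controlled interference field, not their
absolute performance on any particular real dataset.

## Preprocessing chain

1. **Quality control** (`assessChannelQuality`): per 5 s non-overlapping
   window, both wavelengths are band-passed to 0.5–2.5 Hz; the scalp
   coupling index is their correlation, the peak spectral power the
   spectral concentration of their cross-correlation. A window passes iff
   SCI ≥ 0.6 and PSP ≥ 0.1; a channel is pruned iff fewer than 65% of its
   windows pass. Pruned channels become NaN rows and stay NaN everywhere
   downstream. The window length is our choice; the thresholds are the
   established defaults of the SCI/PSP methodology.
2. **Optical density** (`intensityToOD`): \(-\ln(I/\bar I)\) with the
   channel temporal mean as reference — the dominant convention; note the
   result is only zero-mean up to Jensen's inequality.
3. **TDDR** (`tddr`): the derivative of the ≤ 0.5 Hz band is iteratively
   reweighted with Tukey's bisquare (c = 4.685, scale 1.4826 × MAD) until
   the weights change by < 1e−8 (max 50 iterations); the repaired slow
   band is re-integrated and the fast band added back. Baseline jumps are
   suppressed by ~90%. A caveat verified against the reference
   implementation: clean low-frequency oscillations are themselves shrunk
   by up to ~10% in the interior (more at the edges), because the
   bisquare weights act on every sample of a smooth derivative — this is
   a property of the method, not of this implementation.
4. **mBLL** (`odToHemoglobin`): per channel and sample the 2×2 extinction
   system is solved with Gratzer/Prahl molar extinction coefficients
   (converted to the natural-log base), pathlength \(d \times
   DPF(\lambda, age) \times PVF\) with \(PVF = 1/60\) and the general
   age/wavelength DPF polynomial (`ageDPF`).
5. **Semisimulation** (`injectCanonicalHRF`): unit-peak double-gamma HRF
   (response gamma peaking at 6 s minus 1/6 of an undershoot gamma
   peaking at 16 s), scaled to 10 µM (channel 6) and 5 µM (channel 8)
   Δ[HbO] with −amplitude/3 for Δ[HbR], added at every onset. Injection
   happens in concentration units after the mBLL — the amplitudes are
   µM, which fixes the stage unambiguously — and before filtering.
6. **Band-pass** (`bandpassHemo`): zero-phase (forward–backward)
   Butterworth, low-pass 0.09 Hz then high-pass 0.01 Hz, each of design
   order 2.

## Correction methods

All methods operate per species on the band-passed concentration data.

- **CAR** subtracts the mean over non-pruned regular channels. SDCs are
  never consulted. Note the subtracted mean contains 1/16 of whatever
  activation is present — with 15 µM of total injection, every
  non-activated channel inherits ≈ −0.9 µM of spurious "deactivation".
  This overcorrection is intrinsic to the algebra.
- **GCR** computes the SVD of the regular-channel data, smooths each
  spatial singular vector with the Gaussian kernel
  \(G(D)=\exp(-D^2/2\sigma^2)\) (σ = 46° of great-circle arc on the
  scalp sphere — the metric is chosen because σ is specified in degrees),
  reconstructs the spatially smooth ("global") part and subtracts it.
  Two choices the original formulation leaves open: the kernel rows are
  normalised to sum to one, so smoothing is scale-preserving (and the
  identity kernel yields exactly zero output), and *all* singular vectors
  are smoothed.
- **SSR** regresses each regular channel on its Euclidean-nearest SDC of
  the same species with the raw projection coefficient
  \(\alpha = \langle s, y\rangle / \langle s, s\rangle\) (no intercept,
  no prewhitening — the method as defined). A pruned nearest SDC falls
  back to the next-nearest; a zero-variance SDC contributes α = 0.
- **GLM ALL / GLM BH** regress all regular channels of both species on
  the SDC time courses of both species (16 or 4 regressors,
  mean-centred, plus an intercept that keeps channel offsets out of the
  SDC betas) and keep the residual. This is the two-step variant —
  nuisance regression first, task GLM afterwards — which avoids
  task/SDC collinearity in the correction stage. Constant (zero-variance)
  SDC regressors are dropped; with none left the data pass through
  unchanged.

**AR-IRLS solver** (`fitGLM`): iterate {fit; select AR(p) on the
residuals by Levinson–Durbin/BIC up to `maxAROrder` (default ⌈4·fs⌉ ≈ 32
lags, ~4 s); prewhiten X and Y; refit with Tukey-bisquare weights} until
the coefficients move < 1e−4 (max 10 iterations). Standard errors come
from the weighted normal equations on the whitened scale. On strongly
band-limited data the AR filter cannot whiten perfectly (the residual
spectrum is nearly empty outside the band), but it restores enough
effective degrees of freedom that the 16-regressor correction does not
overfit and 95% CIs stay near nominal coverage where OLS collapses to
~60–70%.

## Evaluation layer

Single-trial epochs are [−5, 25) s around each onset (half-open, onsets
snapped to the nearest sample → 234 samples at 7.8125 Hz), baseline
corrected by the [−5, 0) s mean. Metrics, computed at the channel with
the strongest GLM-ALL task beta inside the task ROI:

- **sRMSE**: epoch and canonical template are min–max scaled to [0, 1],
  the epoch is regressed on the template *with an intercept*, and the
  root mean squared residual is returned. Two deliberate deviations from
  a literal reading of the defining formulas: a plain (unsquared) mean of
  residuals is identically zero under an intercept regression, so the
  root-mean-square is used; and the intercept is included because the
  standard regression tooling the metric is defined with includes one.
- **COR**: Spearman ρ against the template, clamped to ±(1−1e−7), then
  Fisher z-transformed.
- **CNR**: mean over peak ± 2 s minus baseline mean, over the square
  root of the summed variances. The root is applied (the printed form of
  such CNRs sometimes omits it; `rootDenominator = FALSE` preserves that
  variant). The peak is searched post-onset only; the window clips at
  epoch edges.
- For Δ[HbR] all three metrics flip the template (or the sign), so
  "higher is better" holds for both species.

Spatial specificity: per trial, Spearman correlations among the 16
regular-channel epochs of the method under test concatenated with the 8
SDC epochs *of the uncorrected data* (the SDC reference must not itself be
corrected away), averaged NaN-ignoring within and then across subjects;
and group beta maps (per-channel across-subject mean task betas with
one-sample JZS Bayes factors).

## Bayes-factor layer

`bfTTest` implements the JZS Bayes factor: a Cauchy prior with scale
√2/2 ("medium") on the standardised effect versus the point null,
integrated numerically on the log scale (inverse-gamma mixture
representation; |t| beyond 1e4 short-circuits to infinite evidence).
`classifyEvidence` applies the conventional ladder at 1/100, 1/30, 1/10,
1/3, 1, 3, 10, 30, 100; a Bayes factor exactly on a boundary is assigned
to the stronger category (documented, arbitrary). No multiplicity
adjustment is applied to Bayes factors. `compareCorMats` runs the 15
pairwise paired tests on the lower-triangular correlation entries per
task and species; repeated-measures Bayesian ANOVA-style omnibus tests
are intentionally out of scope.

## Validation suite sizes

The packaged checks run at sizes chosen to exercise every pathway while
keeping a full run in minutes: the structural-cardinality check uses a
6-subject cohort over both sessions; the qualitative method-ordering
check pools three 10-subject semisimulated cohorts (fixed seeds 1–3);
the solver-calibration check uses 200 replicates of n = 2000 AR(1)
series. The qualitative orderings (SDC methods beat spatial filters on
COR/CNR; every correction beats the uncorrected reference; GLM ALL best
overall; CAR/GCR — and only they — push non-activated channels negative)
are mean-level statements over those cohorts; individual subjects and
small cohorts can and do rank the three SDC methods differently, which
mirrors how close those methods are in practice.

## Known limitations

- The generator's interference field, not real physiology, defines the
  difficulty of the correction problem; the defaults were fixed once
  (table above) and the reported orderings are conditional on them.
- The AR-IRLS implementation follows the published algorithm but is not a
  port of any particular toolbox; numerical results can differ in the
  third decimal from other implementations on identical input.
- SNIRF/HDF5 I/O is not provided; recordings and schedules travel as
  plain TSV (`writeRecordingTSV`, `writeScheduleTSV`).
- Pruning propagates NaN conservatively; methods refuse rather than
  guess when their required inputs are pruned (e.g. GLM BH with SDC 4 or
  7 missing).
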