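---
title: "somnokit: models and methods"
author: "somnokit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{somnokit: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

somnokit analyses rodent sleep-deprivation experiments recorded as
epoch-scored hypnograms (4-s epochs labelled wake / NREM / REM, with
artefact flags), per-epoch EEG power spectra, cortical-temperature traces
and per-minute locomotor-activity (LMA) counts under a 12:12 light-dark
(LD) schedule with a 6-h forced-wake block (sleep deprivation, SD) at
Zeitgeber time (ZT) 0-6 of day 3 of a 4-day recording. This vignette
explains the models the package implements, the conventions and numerical
choices behind them, and what the bundled synthetic-data generator does
and does not emulate.

## The homeostatic Process S

The central model is the homeostatic arm of the two-process model of
sleep regulation. Sleep pressure S (tracked empirically by NREM-sleep EEG
delta power, 0.75-4.0 Hz, in % of a reference) relaxes exponentially
toward an upper asymptote UA during waking and REM sleep and toward a
lower asymptote LA during NREM sleep, stepped once per 4-s epoch:

* wake/REM: `S' = UA - (UA - S) * exp(-dt / tauI)`
* NREM:     `S' = LA + (S - LA) * exp(-dt / tauD)`

with `tauI`, `tauD` in hours and `dt = 4` s. `stepS()` implements one
update; `simulateProcessS()` runs the recursion over a hypnogram using
closed-form within-bout updates (run-length compression), which is
algebraically identical to per-epoch stepping but orders of magnitude
faster. S is clamped to `[LA, UA]` after each update purely as a
floating-point guard; the closed form cannot overshoot analytically.

**Warm-up.** The reported trace must not depend on an arbitrary starting
value. We initialise S at 150% and iterate over the first 24 h of the
hypnogram repeatedly until the value at the start of the day converges
(tolerance 1e-9, capped at 50 passes). A single pass contracts the
dependence on the start value only by `exp(-(t_wake/tauI + t_nrem/tauD))`
— about a factor 75 for realistic constants, which still leaves a few
percent of reference — so we iterate to the fixed point, which is the
precise expression of the steady-state assumption that baseline days are
representative. After convergence, traces started at 0, 150 and 300%
agree to better than 1e-6.

**Asymptote estimation.** `estimateAsymptotes()` takes UA as the 99th
percentile of the NREM delta-power sample of the whole recording, and LA
as the point where the normalized frequency distributions of NREM and REM
delta power intersect between their modes. The crossing uses histograms
on a common grid (bin width 2% of the NREM median), scanning upward from
the REM mode for the first bin where the NREM frequency exceeds the REM
frequency and refining by linear interpolation; when the two
distributions are separated by a run of empty bins, the midpoint of that
run is used, since interpolating between two near-zero counts is
numerically meaningless. Note that the asymptotes of the *generating*
process are not recoverable this way on low-noise synthetic data: with
`tauI` around 13 h, S never approaches its asymptotes within an LD cycle,
so the empirical percentile reflects the attained range of S rather than
UA. Empirical asymptote estimates on real data are driven by the broad
per-epoch scatter of measured delta power.

**Grid search.** `fitGrid()` evaluates every combination of
`tauI` in 1-25 h (step 0.125 h) and `tauD` in 0.1-5.0 h (step 0.025 h),
endpoints inclusive: 193 x 197 = 38,021 simulations. For each grid point
the simulated S is averaged over exactly the NREM epochs that contribute
to each observed time-course bin (rather than sampled at bin midpoints),
and the mean squared difference against the bin values is minimised; ties
break toward the smaller `(tauI, tauD)` pair. The whole sweep is
vectorized across grid points with geometric partial sums inside
run-length-compressed state bouts, so the full grid on a 4-day, 86,400-
epoch recording completes in a few seconds on one core; a 4x-coarsened
grid (2,450 points) is provided for quick exploration. Asymptotes
supplied in raw delta units are converted to the time-course's % scale
via its reference value, exploiting the affine equivariance of the S
recursion.

**Delta-power time course.** `deltaTimecourse()` divides each lights
phase into bins containing an equal number (within one) of artefact-free
NREM epochs that carry a delta value, so bin timing follows NREM
prevalence: 12 bins per baseline or late-recovery light period, 8 for the
post-SD remainder (ZT6-12) of the SD day, 6 per dark period. Bin values
are expressed in % of the reference — the mean delta power over NREM
epochs in ZT8-12 of the baseline days, the daily minimum of sleep
pressure — and bin times are the epoch-weighted midpoints. `detrendDelta()`
removes slow non-biological drift by fitting a straight line through the
three low-pressure reference-window means (ZT8-12 of both baseline days
and of the last recovery day) against recording time and dividing it out;
detrending is multiplicative because delta power is a positive relative
quantity.

## Spectral state metrics

`epochSpectra()` computes per-epoch Hamming-windowed periodograms (800
samples at 200 Hz per 4-s epoch gives the standard 0-100 Hz grid in
0.25-Hz bins). `spectralReference()` forms the per-animal normalization
constant as the mean over the three vigilance states of the state-mean
total power (0.75-45 Hz) in the 48-h baseline — equal state weighting, so
animals with different sleep-wake proportions remain comparable. Band
membership is by bin-center inclusion on closed intervals, so the 4.0-Hz
bin belongs to the delta band exactly once.

Theta-peak frequency (`thetaPeakFrequency()`) is the frequency of the
per-epoch spectral maximum within 6.5-12 Hz for theta-dominated waking
(TDW) and 5.5-12 Hz for REM sleep, averaged over artefact-free epochs.
TDW classification (`classifyTdw()`) thresholds the share of 6.5-12 Hz
power in the 0.75-45 Hz total of each wake epoch; the default threshold
is the valley between the two modes of the wake-epoch ratio distribution
(kernel density, with an Otsu-style minimum-within-class-variance
fallback when the density is not clearly bimodal), which realises the
"relative theta importance" criterion without hard-coding a constant. The
"total" is taken over 0.75-45 Hz to match the reference band; the full
0-100 Hz grid would dilute the ratio with gamma and line noise.

## Thermometry

The thermistor is an NTC bead driven by a constant 100-uA current.
`calibrateThermistor()` derives the material constant
`beta = T25*T37/(T25-T37) * ln(R37/R25)` (kelvin; natural logarithm —
required for the conversion to return exactly 25 and 37 deg C at the two
calibration resistances), and `temperatureFromVoltage()` converts the
median voltage per 4-s epoch of a 10-Hz stream via `Rt = V/I` and the
inverted beta equation. `temperatureQc()` reports each animal's daily
amplitude (mean over baseline days of the hourly-mean range) and its
SD-window mean — a state-controlled level estimate since all animals are
awake throughout the SD — flags median-absolute-deviation outliers in
both, and offset-corrects level outliers to the cohort mean; amplitude
outliers are only flagged, never silently removed.

`transitionProfiles()` aligns temperature on transitions between
consolidated bouts (both flanking states at least 8 epochs, i.e. more
than 32 s), references each trace to the anchor (mean of the last pre-
and first post-transition epoch), and truncates the mean profile wherever
fewer than 10 transitions contribute; each transition contributes only
within its own flanking bouts, so sparse kinds yield naturally shorter
profiles. The window is fixed at +/-90 s; combined with the support rule
this reproduces differing plotted lengths per transition kind.

`wakeTemperatureAssociation()` gives ordinary R2 of hourly temperature on
waking and on LMA separately, and the partial correlation of temperature
with each predictor controlling for the other, computed from the
closed-form pairwise-correlation recursion (identical to correlating the
two regression residual sets; the tests verify the equivalence to 1e-12).
When one predictor explains the response exactly the other's partial
correlation is reported as 0. Fisher Z (atanh) transforms accompany the
coefficients for cross-animal comparison. LMA is log2(counts + 1) per
hour throughout; hourly waking is in minutes per hour.
`residualSineFit()` fits `b + A sin(2 pi t/24 + phi)` to the wake-only
regression residuals by linear least squares in `(b, A cos phi, A sin
phi)`, reporting a non-negative amplitude and a phase in [0, 24) h.

`mixedModelCompare()` fits three nested linear mixed models of hourly
temperature with a per-animal random intercept (maximum likelihood):
waking alone; plus LMA per unit waking; plus their interaction. Models
are compared by likelihood-ratio chi-squared tests, and marginal /
conditional R2 follow the Nakagawa variance decomposition (fixed-effect
variance over, respectively with, the random-intercept variance and the
residual). The random-intercept structure is the minimal one that
accounts for stable between-animal temperature differences.

## Recovery accounting and screening

`accumulatedDifference()` accumulates hourly recovery-minus-baseline
minutes in a state from the end of the SD; recovery hours are matched to
the baseline day two days earlier (REC1 vs BL1, REC2 vs BL2), with an
averaged-baseline option. `lmaPerWakingTimecourse()` expresses movement
counts per waking minute in bins of equal accumulated waking time (6 per
light phase, 12 per dark, 6 during the SD, 3 for the post-SD light
remainder); minutes are assigned to bins by their cumulative-waking
midpoint, which bounds each bin's waking total within one minute of the
equal share, and counts in minutes without waking carry zero weight.
`madOutliers()` flags values more than 3 robust SDs (1.4826 x MAD) from
the median — the conventional scaling and cut, since the outlier test is
named in the field without a threshold.

## qPCR quantities

`extComRatio()` is the efficiency-based isoform ratio
`E^(Ct_comm - Ct_ext)` for an extended/common 3'UTR primer pair.
`normalizedRelativeQuantity()` computes `RQ = E^(Ct_mean - Ct)` per gene,
normalizes each sample by the geometric mean of its reference-gene RQs
(the standard multi-reference scheme), then rescales each gene's grand
mean to 1; log2-NRQs accompany the output. Normalization happens before
the grand-mean rescale; the order matters only for the intermediate
`nrq_raw` column, which is kept for closed-form checks. Genes with mean
Ct above 30 cycles are flagged unreliable but never silently dropped.

## The synthetic-study generator

`generateStudy()` produces a complete 96-h bundle with known ground
truth, so every stage of the pipeline is testable without animal data.

* **Hypnogram** — a semi-Markov chain alternating wake and NREM with
  NREM -> REM -> (wake | NREM) branching. Dwell means and branching
  probabilities are phase-dependent and calibrated to published baseline
  budgets (per 12 h: NREM 389/189 min, REM 70/19 min, wake 260/512 min,
  TDW 45/179 min in light/dark). Wake and NREM dwell times are mixtures
  of brief (mean 2 epochs) and consolidated bouts — sleep in mice is
  fragmented, and only a minority of bouts reach the 8-epoch
  consolidation criterion, which calibrates the census of qualifying
  wake-to-NREM transitions to a few dozen per two baseline days. REM
  dwells are negative-binomial around ~1 min. The SD window is forced to
  wake with a small intrusion hazard (about 99.5% wakefulness; gentle
  handling is imperfect), and the 18 h after SD carry a linearly decaying
  multiplicative increase in sleep propensity — a phenomenological
  rebound, deliberately not fed back from Process S so the generator
  stays independent of the model under test.
* **Delta power** — the configured true Process S (defaults on-grid:
  tauI 13 h, tauD 3 h, UA 290%, LA 45%) times multiplicative lognormal
  noise of mean 1 and CV 0.10, on artefact-free NREM epochs only;
  optionally low REM-epoch delta for end-to-end asymptote estimation.
* **Spectra** — per-state templates (1/f background plus a delta peak at
  2 Hz for NREM, theta peaks at 7.5 Hz for REM and 8.1 Hz for TDW) times
  per-epoch and per-bin lognormal jitter.
* **Temperature and LMA** — Poisson movement counts per waking minute
  with dark-phase dominance and exact zeros in sleep-only minutes;
  temperature relaxes first-order toward a state asymptote (NREM 35.4,
  REM 36.2, wake 36.3 deg C; time constants 200/75/180 s) raised in
  proportion to the minute's activity, so REM entries produce the
  characteristic fast rise (~0.4 deg C within 1.5 min) and NREM entries a
  fall.
* **qPCR plate** — two flat reference genes, targets with configured
  per-group fold changes, an ext/comm pair with a fixed cycle offset, and
  Gaussian Ct noise.

Everything is deterministic under the configuration seed.

**What the generator does not emulate.** Raw EEG waveforms (spectra are
drawn directly); per-state 1/f exponents; the circadian modulation of
temperature beyond what the sleep-wake distribution induces (the daily
amplitude is about 1 deg C versus about 2.3 in vivo, and the wake-only
regression residuals carry no built-in 24-h rhythm); the initial
temperature dip at REM-to-wake transitions; EMG; and any feedback from
sleep pressure onto sleep-wake structure. Consequently, passing tests
demonstrate the correctness and calibration of the analysis machinery on
data with known truth — not that real recordings satisfy the model.

Two further emulation limits are deliberate. First, because S never
attains its asymptotes within an LD cycle, the distribution-based
asymptote estimators are exercised on constructed samples with known
crossings rather than on generator truth. Second, under the package's
per-minute state rule (modal state of 15 epochs, ties broken
WAKE > NREM > REM — the rule itself is a documented convention, since the
original per-minute displays do not state one) REM sleep is represented
near-proportionally rather than slightly under-represented: a bout facing
consolidated neighbours wins, in expectation, exactly its length in
minutes.

## Problem sizes and runtime choices

The test suite and the acceptance script run on 4-day, 86,400-epoch
recordings. Full-grid fits (38,021 points) are used where exactness is
asserted; repeated-seed recovery and cohort-null checks use the
4x-coarsened grid, whose 0.5 h / 0.1 h steps still resolve the stated
recovery tolerances. Spectra are generated for 1-day subsets (21,600 x
401 matrices) where per-epoch spectral content is needed; a full 4-day
spectral matrix (~280 MB) is never materialised in tests. Mixed-model
power checks use 6 animals x 96 h over 20 seeds per scenario.

## Known limitations

* The grid fit assumes the asymptotes are fixed before the sweep;
  joint estimation of asymptotes and time constants is out of scope.
* `fitGrid()` compares bin means, not raw epochs; with very few NREM
  epochs per bin the averaging loses little information, but an
  unbinned per-epoch MSE is not offered as a default.
* The LA crossing estimator needs both distributions' modes in the
  right order and errors out otherwise, advising a manual LA.
* Mixed models fit a random intercept only; random slopes are left to
  the user via lme4 directly.
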