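---
title: "lcpipe: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lcpipe: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcpipe)
```

This vignette is the package's own account of the science behind each
analysis stage: the model or procedure, its assumptions, the parameters
that matter, and the choices we made where the design was genuinely open.
Everything quantitative stated here is computed by the test suite or by
`scripts/acceptance.R`; nothing is quoted from elsewhere.

## Ratiometric screening

The yellow Cameleon FRET sensor reports intracellular calcium through two
emission channels that move in opposite directions: a calcium rise
increases YFP and decreases CFP emission, so the per-ROI YFP/CFP ratio
(`compute_yc_ratio()`) carries the calcium signal while channel-common
nuisances — excitation fluctuations, photobleaching — cancel to first
order. This ratio-metric robustness is the reason the whole screening
analysis operates on Y/C rather than on either channel.

**Correction and Z-scoring.** For each substance application session,
`correct_and_zscore()` fits a linear trend to the ratio over the 5-min
pre-application baseline, removes it from the whole segment, and converts
to Z units using the baseline mean and SD. The exact correction used by
the original screening software is not public, so the detrend is exposed
as a strategy hook: the default is ordinary least squares, with Huber
M-estimation (`method = "rlm"`) available when baseline transients are a
concern. We default to least squares because M-estimation is undefined on
the degenerate zero-noise baselines the synthetic tests exercise (the MAD
scale estimate collapses), and because on clean baselines the two agree.
A baseline whose detrended SD is numerically zero (relative to the signal
scale) raises an error rather than producing infinite Z values.

Z-scoring is invariant to affine transforms of the raw ratio, which the
tests assert directly: gain and offset shift the fitted trend and the
baseline statistics together.

**Response windows.** `mean_response()` averages Z over half-open windows
relative to application onset: 0–5 min for screening classification, and
10–11 min for the genotype comparisons where a late time point indexes
sustained suppression. Windows are half-open `[a, b)` in time; frame `i`
maps to time `(i − 1) · frame_interval`. Indices are 1-based everywhere
in reports, matching R convention.

**Classification.** `classify_substance()` pools per-ROI 5-min mean
Z-scores across slices and computes quartiles by linear interpolation of
order statistics at positions `p(n − 1)` (the `stats::quantile()` type-7
default, the dominant convention in scientific software). Q3 > 2 calls an
increase, Q1 < −2 a decrease. The ±2 cut is deliberately conservative —
it asks a quarter of the pooled ROI population to move beyond 2 baseline
SDs. A sample meeting both criteria at once is bimodal and raises an
error instead of a silent label.

**FWHM.** `fwhm()` measures the duration of a suppression transient: the
minimum of the centered 120-frame moving average of Z (`z_min120`), then
the first and last frames at which the *raw* Z is strictly below half
that minimum. We chose a centered window (truncated at the edges) for its
symmetric bias; the alignment is recorded in the function contract.
Comparisons use strict `<` exactly as the rule is stated; ties are
impossible on continuous data and otherwise resolve to the first/last
index by the scan itself. ROIs whose 5-min mean Z is not below −2 never
showed a clear decrease and are excluded (`excluded = TRUE`); a crossing
touching the recording edge is flagged `censored`. Because the first/last
crossing of a noisy trace is an extreme statistic, measured FWHM on noisy
data is upward-biased relative to the generating kernel; the recovery
tests therefore validate FWHM on the noiseless kernel path and validate
the smoothed minimum (which averages noise down) on the noisy path.

**Peak ΔR/R₀.** For electrophysiological confirmation the raw
(uncorrected) ratio is used: `peak_dr_over_r0()` subtracts the mean ratio
over the 30 s before the stimulus (R₀) from the in-stimulus peak and
divides by R₀. The statistic is invariant to rescaling the whole trace.

**Session orchestration.** `screen_session()` walks the annotated
applications of a recording; each session segment runs from 5 min before
onset to the start of the next application's baseline. An application too
close to its predecessor (no clean baseline) is flagged and carried as
`NA`, never silently dropped. `screen_cohort()` pools slices before
classification, since the quartile rule is defined on the combined ROI
population.

## The synthetic slice-imaging generator

`generate_yc_recording()` encodes a latent relative ratio modulation
`s(t)` into the two channels as `YFP ∝ sqrt(1 + s)` and
`CFP ∝ 1 / sqrt(1 + s)`, which makes the channels exactly
anti-correlated and the ratio exactly `∝ (1 + s)`. A shared
single-exponential bleach (`bleach_tau`, default 3600 s) multiplies both
channels, so the ratio is bleach-insensitive — mirroring the motivation
for the ratiometric sensor — and independent multiplicative white noise
(`noise_sd`, default 1%) is applied per channel.

Response depth is specified in Z units of baseline ratio noise: with
relative channel noise σ, the relative ratio noise is √2·σ to first
order, and the kernel is scaled so a downstream Z-score reaches `depth`
at the peak. This couples the generator to the analysis contract rather
than to arbitrary absolute amplitudes.

The response kernel (`response_kernel()`) is a half-Gaussian rise
(default `rise_sd` 30 s, on the order of perfusion wash-in) joined to a
half-Gaussian decay whose width is solved so that the kernel FWHM equals
`duration_fwhm` *exactly* — the closed form is what makes the kernel
usable as an FWHM ground-truth oracle. The kernel is clipped to zero
before onset + delay; the peak sits 2.5 rise-SDs later, so the clipped
tail is below 0.05 of the peak.

Default study conditions used by the calibration runs: 2-min
applications, 5-min pre-onset baselines, 1-s frame interval (the
acquisition interval is instrument-specific, so `frame_interval` is a
required argument with no default), 12 ROIs per slice, 2 slices per
cohort, depth 4 Z at responder fraction 0.75 for responsive cohorts. What
the generator does *not* emulate: focus drifts and motion (the pipeline
enters at ROI-intensity level, after image registration), correlated
noise across ROIs, and multi-peaked or oscillatory responses. Passing
tests therefore certify the trace-level analysis, not image processing.

## Tail-suspension immobility

A tail-suspended animal's body-area time series mixes two oscillatory
processes: passive pendulous swinging (narrowband, low frequency) and
active struggling (broadband, faster). `struggle_signal()` computes an
analytic Morlet continuous wavelet transform (ω₀ = 6; FFT
implementation with zero padding) and takes the mean coefficient
magnitude across scales in the struggle band only — default 2.5–10 Hz,
with the pendulum band (default 0.2–2 Hz) excluded. Whether the original
struggle signal was a single-scale reconstruction or a band marginal is
not documented; we chose the band marginal because it is insensitive to
the exact pendulum frequency and makes the separation property testable
with pure tones (a pendulum-band tone produces under 5% of the response
of an equal-amplitude struggle-band tone in the tests).

`score_immobility()` thresholds at σ_WLT/2, where σ_WLT is the SD of the
full-session struggle signal. The SD uses population (n) normalization by
default so that the scorer's worked arithmetic examples are exact
(`sd_type = "sample"` is available); at behavioral series lengths the
difference is negligible, and the immobility mask itself is identical
under either choice in all tested cases. Because the threshold scales
with the signal, the mask is invariant under positive rescaling of
TS_WLT — asserted as a property test. No minimum bout duration or mask
smoothing is applied by default (none is specified for the method);
epochs are built directly from mask transitions as (mobile, immobile)
pairs, leaving a leading immobile run or trailing mobile run unpaired.
Manual correction of fiber-tethered videos is out of scope; the mask is
exported for external editing and can be re-imported.

The generator (`generate_tst_area_series()`) sums a constant body area,
an always-on pendulum tone (0.75 Hz default), band-limited struggle
noise inside the declared bouts, and white noise, at a default
struggle-to-noise amplitude ratio of about 6.7. It does not emulate
slow postural drift, camera artifacts, or the fiber-cable artifacts that
motivate manual correction in vivo.

## Vigilance staging

`epoch_features()` computes per-4-s-epoch features: δ (1.5–4 Hz) and θ
(5–8 Hz) EEG band amplitudes, their ratio, EMG RMS, and summed IR
activity counts. "Amplitude" is implemented as the RMS of the
zero-phase band-passed signal per epoch — the original software's exact
definition (RMS vs peak vs spectral power) is not documented, and RMS is
the choice most robust to single-sample artifacts. Band-pass filters are
4th-order Butterworth applied with `filtfilt`, consistent with the
acquisition filters (EEG 1.5–30 Hz, EMG 15–300 Hz); when the sampling
rate cannot support the EMG upper edge, it is capped at 0.45·fs.

`stage_epochs()` applies the printed rule cascade in fixed order, first
match wins: high IR → W, high EMG → W, high δ → NR, θ ratio above 1 → R,
otherwise the epoch copies the previous label (initial state W, since
recordings begin with handling-induced wakefulness). "Higher" thresholds
are unspecified in the source method, and absolute thresholds would not
transfer across animals with different electrode gains, so defaults are
per-recording percentiles: IR and EMG 75th, δ 60th, θ ratio fixed at 1
(a gain-free quantity). All are overridable — and must be overridden
with absolute values for recordings without state diversity (an all-REM
recording has no meaningful within-recording percentiles).

The generator builds the EEG as state-gained δ-band, θ-band and
broadband noise components (NR elevates δ ×3, R elevates θ with a θ/δ
ratio near 2, W elevates EMG ×3 and the IR event rate), with per-epoch
lognormal gain jitter (SD log 0.2) as the default noise condition. The
24-h calibration uses a Markov state sequence with rodent-like bout
persistence at 100 Hz sampling; the module tests use 1-h sequences at
the same rate. Real EEG nonstationarities — artifacts, transitional
epochs, state-dependent spectral slopes — are not emulated, so staging
accuracy on synthetic data is an upper bound on real-data performance.

## Fiber photometry

The acquisition interleaves 470-nm (calcium-dependent) and 405-nm
(isosbestic) excitation at 20 Hz, 25 ms each, sampled at 1 kHz.
`deinterleave()` averages samples 13–24 (1-based, inclusive — 12
samples) of each 25-sample burst, discarding the first 12 and the last
sample as LED settling/transition points, yielding 20 Hz series per
channel. The synthetic generator optionally injects a settling transient
on exactly the discarded samples, so the round-trip is exact by
construction when bursts are clean.

`isosbestic_correct()` computes `F_GC = F470 − F405 · µ470/µ405` with
the µ's taken over the first third of each series. Whether "first third"
refers to the full recording or only the behavioral-test window is
ambiguous in the method's description; we take the full recording, since
the correction is defined before any behavioral windowing, and document
the choice here. Artifacts that modulate both channels proportionally
cancel exactly — a property test drives the artifact amplitude and
checks the residual.

`smooth_and_normalize()` applies a 10-point moving average (trailing,
truncated at the start — the causal reading of an unqualified "moving
average"; a centered variant is available) and min-max normalizes to
[0, 1]. `epoch_normalize()` rescales each mobile–immobile epoch by its
mobile-period maximum and immobile-period minimum; `F_Eonset` is the
rescaled value at the first immobile sample. Values outside [0, 1] away
from the two anchor samples are legitimate and are not clipped. Epochs
with `F_Emax ≤ F_Emin` are flagged invalid and excluded from the
per-animal mean. PMT voltages are negative-going at the default
operating points (−1 V and −0.5 V for 470 and 405 nm); all operations
are sign-agnostic, and the earlier-vs-later suppression ordering test
inverts the normalized trace for the behavioral contrast, as one would
for plotting.

## Clustered statistics

ROIs from the same animal are correlated, so ROI counts overstate the
evidence. `icc_oneway()` implements the one-way random-effects ANOVA
estimator `ICC = (MSB − MSW) / (MSB + (m̄ − 1)·MSW)` with the
unbalanced-adjusted mean cluster size `m̄ = (N − Σmᵢ²/N)/(k − 1)`; a
brute-force sums-of-squares oracle checks it exactly in the tests.
`effective_sample_size()` applies the design-effect formula
`n_eff = n / (1 + (m̄ − 1)·ICC)`. Negative ICC estimates are reported
as-is but clipped to zero inside the design-effect formula, where
negative clustering has no meaning. The reference implementation this
mirrors is the ANOVA estimator of the R ICC package; if that package's
internal n_eff convention differs from the plain design-effect formula,
the numbers here follow the formula as stated.

Mixed-model comparisons are deliberately delegated, not re-implemented:
`fit_group_comparison()` wraps `nlme::lme()` with random intercepts per
cluster (optionally nested, e.g. animal/ROI), marginal Wald F tests, and
Tukey-adjusted pairwise contrasts via emmeans when the focal factor has
more than two levels. The wrapper's job is specification bookkeeping and
a reproducible report; singular fits surface the underlying error.
Simulation tests check the delegation end to end: exact null estimates
on mirrored data, agreement with OLS when clusters are singletons, and
confidence-interval coverage of an injected shift near the nominal level
(slightly below 95% is expected with 20 clusters, where REML variance
uncertainty is not accounted for by the Wald interval).

## Problem sizes and numerical notes

The calibration runs use sizes chosen to make sampling error small
relative to the margins being tested: 200 cohorts per screening
condition; 1,000 random traces for FWHM oracle equivalence plus seven
noiseless kernels from 100–400 s; 100 seeded tail-suspension sessions of
6 min at 30 Hz; one 24-h staging recording (21,600 epochs) at 100 Hz;
500 Monte-Carlo replicates for ICC calibration at k = m = 20. All
generators take explicit integer seeds and are byte-reproducible;
seeded cases in the suite are property-style loops over many draws.

Degenerate inputs fail loudly by policy: constant baselines, zero
struggle variance, constant F_TS, empty epochs, single clusters, and
schedule gaps all raise errors naming the condition, because each one
silently invalidates the statistic that would otherwise be produced.

## Known limitations

- The pipeline starts at ROI/trace level; image registration, ROI
  segmentation and video-to-area extraction are out of scope.
- FWHM via first/last strict threshold crossing is an extreme statistic
  and inherits upward bias on noisy traces (see above); it is the
  method's definition, not an estimator we are free to robustify.
- Synthetic benchmarks certify internal consistency (generator →
  analysis recovery), not performance on real recordings; the generators'
  realism limits are listed per module above.
- EDF ingestion is not provided; EEG/EMG/IR enter as numeric series
  (CSV-friendly), which the staging functions consume directly.
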