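---
title: "Short-term fractal scaling of heart rate variability: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Short-term fractal scaling of heart rate variability: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fractalHRV)
```

## The index and the thresholds

During incremental exercise the beat-to-beat (RR) interval series loses its
fractal structure in a characteristic way. The short-term scaling exponent of
detrended fluctuation analysis (DFA alpha1) quantifies that structure: values
near 1 indicate well-correlated, fractal beat patterns typical of low
intensity; 0.5 indicates uncorrelated (random) beats; values below 0.5
indicate anticorrelated behaviour seen only at severe intensity. Because
alpha1 moves through this whole range as work rate rises, the intensities at
which it crosses two fixed values serve as autonomically derived surrogates
for the conventional physiologic thresholds:

* **HRVT** — the heart rate (or time, or power) at which alpha1 crosses
  **0.75**, a surrogate for the first ventilatory/lactate threshold;
* **HRVT2** — the crossing of **0.5**, a surrogate for the second threshold.

This package implements the full chain needed to estimate both from a plain
RR recording: artifact handling, per-window detrending, rolling alpha1
computation, and threshold interpolation, together with a synthetic generator
that plants known thresholds so every stage can be validated.

## The processing chain

The chain is `correct -> window -> detrend -> DFA -> thresholds`, fixed in
this order. Artifact correction operates once on the whole recording;
detrending is per analysis window, immediately before DFA, matching the
time-varying computation style of the established HRV analysis tools.

### DFA alpha1 (`dfa_alpha1`)

Per window: subtract the mean, integrate by cumulative sum, split the profile
into non-overlapping boxes of $n$ beats for $n = 4 \dots 16$ (trailing
partial box discarded), fit a least-squares line per box, and form the RMS
residual $F(n)$ over all covered points. alpha1 is the least-squares slope of
$\log F(n)$ versus $\log n$.

**Finite-size correction.** At these short box sizes $E[F^2(n)]$ is not
proportional to $n^{2H}$ even for exact fractional Gaussian noise: for
uncorrelated data the exact expectation is $\sigma^2 (n^2-4)/(15n)$, and a
naive slope over boxes 4–16 reads ≈ 0.58 for white noise instead of 0.5. The
estimator therefore rescales the fluctuations by the closed-form fGn
expectation $E[F^2(n; H_0)] = \mathrm{tr}(M \Sigma_{H_0})/n$ ($M$ the in-box
linear-detrend residual maker, $\Sigma_{H_0}$ the fGn profile covariance) at
a provisional exponent and refits, twice. Residual bias is below 0.01 across
$H \in [0.3, 0.95]$ and about $-0.035$ at $H = 1$; the correction preserves
the estimator's exact affine invariance. Without this step the uncorrelated
anchor (0.5) and the anticorrelated regime could not be read off at face
value from 4–16-beat boxes.

### Rolling computation (`alpha1_rolling`)

Windows are 2 min wide, recomputed every 5 s, and right-aligned (a window is
stamped at its end, the causal/real-time convention; centre assignment would
shift threshold *times* but changes threshold *heart rates* little, since HR
is windowed identically). Windows need at least 100 beats; below that they
are invalid rather than extrapolated. Windows whose corrected-beat share
exceeds 5% are flagged invalid for field use; the artifact experiments lift
this screen deliberately. A beat-count streaming mode (`alpha1_realtime`,
prior 200 beats per emission) matches the batch chain exactly on identical
beat windows.

### Smoothness-priors detrending (`sp_detrend`)

The slow trend of each window is removed by the regularised fit
$\hat{z}_{trend} = (I + \lambda^2 D_2^T D_2)^{-1} z$ with second-difference
operator $D_2$ and $\lambda = 500$ (the HRV-preprocessing convention; it acts
as a high-pass with a cutoff far above the 4–16-beat DFA boxes, so its effect
on alpha1 is small but it stabilises windows that straddle load transitions).
The window mean is removed first and not restored. $\lambda = 0$ degenerates
to "trend = signal" and returns zeros.

### Artifact handling

*Threshold detection* flags beat $i$ when $|rr_i - \mathrm{med}_i|$ exceeds a
named absolute level (very_low 0.45 s … very_strong 0.05 s, default medium
0.25 s), where $\mathrm{med}_i$ is the median of the 11 nearest intervals
centred on $i$, the candidate itself excluded. Excluding only the candidate —
rather than iteratively re-excluding flagged beats — keeps the rule
deterministic and guarantees that stricter levels flag supersets of looser
ones.

*Automatic detection* is a successive-difference robust-z classifier: within
a 91-beat context the quartile deviation of successive differences sets the
scale, and a beat is flagged when the smaller of its two adjacent jumps
exceeds 5.2 scales (demanding both a large jump in and out isolates the
aberrant beat rather than its neighbours), or when an interval sits near
twice the local median (the missed-beat signature).

*Correction* replaces flagged intervals by cubic-spline interpolation through
the non-flagged intervals. An interval above 1.75× the local median is first
split into $k = \mathrm{round}(rr/\mathrm{med})$ sub-intervals, and the
imputed values are rescaled so each split conserves its original sum — total
recording duration is conserved exactly for every missed-beat repair, and the
beat count is restored.

*Injection* (`inject_missed_beats`) emulates dropped QRS detections for the
bias experiment: interior beats are deleted uniformly at random (no two
adjacent), each deletion merging two intervals into their sum, conserving
duration exactly.

### Threshold estimation (`hrvt`)

The estimator regresses alpha1 on the predictor (HR by default; time and
power are available because published protocols report all three) and solves
for the crossing. Numerical choices that matter:

* **Regression band.** Only windows with alpha1 in $[0.4, 1.0]$ participate,
  excluding the pre-ramp correlated plateau and the anticorrelated floor. The
  in-band set is the *contiguous run* of windows between the smoothed
  (4-point trailing mean) trace's entry into and exit from the band.
  Thresholding individual windows instead would censor noise asymmetrically
  at both band edges and dilute the slope by ~15%, displacing HRVT2 by
  several bpm — selection on trajectory position leaves OLS unbiased.
* **Fallback.** If $r^2 < 0.5$ or the slope is not negative, the estimator
  falls back to first-crossing linear interpolation on the smoothed trace,
  with a `poor_fit` QC flag; with multiple crossings the first in time is
  used and flagged. If the smoothed trace never reaches a target the
  estimate carries `no_crossing` and no value.
* **Ordering QC.** When both targets are estimated, HRVT2 must not come at a
  lower heart rate than HRVT; violations flag both estimates
  `inconsistent_order`.
* On exactly affine input the crossing is exact to numerical precision, and
  adding a constant to every window's HR shifts the estimate by exactly that
  constant.

## The synthetic test bed

`generate_fgn` draws exact fractional Gaussian noise by circulant embedding
of the fGn autocovariance (eigenvalues are provably non-negative, so the
synthesis is exact for $H < 1$); for $H \ge 1$, where stationary fGn does not
exist, a $1/f^{2H-1}$ surrogate is shaped in the spectral domain. Output is
standardised; the lag-1 autocorrelation matches $2^{2H-1}-1$.

`generate_exercise_ramp` realises piecewise-stationary segments (per-segment
exponent, mean RR, RR sd) joined by 30-s linear cross-fades of mean and sd.
The built-in `clean_ramp` emulates a 20-min incremental test: exponent 1.1 at
rest falling linearly to 0.3 at peak in 30-s stages, heart rate rising
linearly from ~71 to ~182 bpm (mean RR therefore spaced harmonically,
850 → 330 ms), and RR variability shrinking geometrically 40 → 3 ms to mimic
vagal withdrawal. Design notes:

* 30-s stages with 30-s fades make the programmed trajectory continuous and
  piecewise-linear, so the planted crossings (the truth log's HRVT/HRVT2) are
  unambiguous; a coarse staircase would leave the "true" crossing undefined
  up to half a stage relative to any window-smoothed measurement.
* Linear HR (not linear RR) matches how incremental ramps actually look and
  yields the near-straight alpha1-vs-HR drop on which linear interpolation
  of the thresholds rests.
* The variance-vs-intensity profile is a plausibility device, not a
  validated model; no quantitative profile is established in the literature.

What the generator deliberately does **not** contain: respiratory sinus
arrhythmia or any quasi-periodic structure, ectopy morphology, device
quantisation, or HR drift at constant load. Passing tests therefore
demonstrate the correctness of the computational chain on controlled fractal
input, not performance on real recordings.

## The artifact-bias experiment

`artifact_bias_experiment` and `hrvt_robustness` reproduce the
missed-beat-robustness study design on synthetic ramps: per seed, a clean
ramp is analysed (control), then 1/3/6% of beats are deleted, detected,
corrected, and re-analysed; windows are matched by end time and compared.

Measured behaviour (threshold-medium correction, clean_ramp): at 1–3% the
mean alpha1 bias is below 0.01 — negligible. At 6% the proportional bias
falls monotonically with the control alpha1, from about +5% on anticorrelated
windows to about +0.5% on correlated ones, and the HRVT shifts by ~1.5 bpm
(median over seeds).

Two aspects of the reference behaviour on real recordings do **not**
reproduce here, for a reason worth stating precisely: deterministic spline
imputation can only *remove* innovation variance (imputed beats are smoother
than real ones), so on pure-fGn input the bias is positive at every alpha1
level and the threshold shift, while small, stays slightly above 1 bpm. The
sign flip to *negative* bias on well-correlated (resting) windows seen on
real data plausibly requires disruption of quasi-periodic respiratory
structure — exactly what the generator excludes by design. A beat-time-domain
peak-insertion correction was evaluated as an alternative and produced
*stronger* smoothing (larger positive bias), so the interval-domain rule is
retained.

## Problem sizes and runtime choices

Simulation-backed checks use fixed seeds and the following sizes, chosen so
the whole suite runs comfortably on a single CPU: regime anchors and
estimator closure at $n = 1000$ beats with 100–200 replicates; ramp-level
experiments on the 20-min `clean_ramp` with 8–20 seeds; drift recovery on
1-h constant-load sessions with 4 seeds. Sampling noise at these sizes is
documented next to each tolerance in the tests.

## Known limitations

* alpha1 near and above 1 is estimated with a mild negative bias (~0.03); the
  finite-size correction is exact only for stationary fGn ($H < 1$).
* The alpha trace is beat-centred while window HR is time-centred, so the two
  lag each other by ~15–25 s on a ramp; in HR terms this contributes ≲ 2 bpm,
  within the method's field accuracy.
* HRVT2 sits near the lower band edge and inherits more extrapolation error
  than HRVT (about 4 vs 2 bpm median on synthetic ramps), consistent with the
  wider agreement limits reported for second-threshold surrogates.
* Thresholds from recordings that lack a monotone intensity ramp (intervals,
  free training) are not meaningful; use the analysis bounds to isolate the
  ramp segment.
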