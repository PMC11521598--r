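---
title: "Methods: dyadic physiological synchrony and shared-emotion analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dyadic physiological synchrony and shared-emotion analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and design

`dyadsync` analyses shared emotional experiences in dyads: two unacquainted
people watch the same emotion-eliciting videos while cardiac (ECG),
respiratory (belt) and electrodermal (skin conductance, SC) activity is
recorded, and rate afterwards their emotional experience and their feelings
toward each other. The package covers five stages:

1. **Synthetic dyad generation** with a controllable inter-member coupling
   parameter, so every downstream stage can be tested against known ground
   truth without human data.
2. **Per-channel preprocessing**: R-peak detection and inter-beat-interval
   (IBI) series construction, expiration-onset detection, phasic SC
   extraction, plus artifact and statistical-outlier screening.
3. **Interpersonal synchrony** by wavelet transform coherence (WTC) with
   cone-of-influence (COI) exclusion, band-restricted averaging,
   correlational alternatives, and a surrogate-dyad bootstrap null.
4. **Dyad-level indices**: dyadic means, absolute differences, mutual
   products, change scores, and neutral-baseline correction.
5. **Mixed-effects modelling** with likelihood-ratio-driven backward
   stepwise selection.

## The synthetic dyad generator

### Latent arousal drivers

The stimulus-locked emotional response is modelled as a band-limited
Gaussian process on 0.01–0.4 Hz (`make_driver`), standardized to unit
variance. This band overlaps the analysed heart-rate-variability bands
(LF 0.05–0.15 Hz, HF 0.15–0.4 Hz), so inter-member coupling is detectable
by WTC. Each video contributes one *common* driver per dyad and one
*idiosyncratic* driver per member; a member's driver is

  `coupling * common + (1 - coupling) * idiosyncratic`,

with both components standardized before mixing and the mixture
restandardized. The implied cross-member correlation is
`c^2 / (c^2 + (1 - c)^2)`, which is zero at `c = 0`, one at `c = 1`, and
strictly increasing in between. The default is `coupling = 0`: in the
study design this package emulates, co-present dyads showed no excess
synchrony over surrogate pairs, so the faithful default is uncoupled
members. Tests and power analyses pass explicit non-zero values.

### Channels

* **IBI**: instantaneous interval `mean_ibi_ms - ibi_sd_ms * a(t)` (higher
  arousal shortens the interval; the gain equals `ibi_sd_ms`, in ms per
  unit driver, so the configured SD is also the modulation depth). Beats
  are laid down sequentially starting half an interval into the record,
  which keeps the first QRS complex clear of the record edge.
* **ECG**: a biphasic Mexican-hat pulse of 80 ms support and 1 mV apex at
  each beat time, plus white noise; ground-truth R-peak times are
  retained. The default 1 kHz rate gives millisecond R-peak accuracy.
* **Respiration**: a sinusoidal tidal-volume proxy whose instantaneous
  rate is the configured rate plus 1 breath/min per unit driver;
  ground-truth expiration onsets (phase maxima) are retained. Sampled at
  100 Hz — breathing content lives far below 5 Hz, so nothing is lost
  relative to a 1 kHz acquisition.
* **Skin conductance**: tonic level plus slow drift plus discrete skin
  conductance responses (SCRs) from an arousal-modulated Poisson process,
  convolved with a two-exponential kernel (0.75 s rise, 2 s decay).
  Sampled at 100 Hz.

Defaults are calibrated to resting values typical of seated young adults
watching 5-min videos: mean IBI 800 ms baseline, respiratory rate
19.9/min, SC level 4.8 uS, 4 SCRs/min. `apply_valence_effects` shifts the
set points per emotional condition (neutral −12 ms IBI; negative +8 ms
IBI, +1.0 breaths/min, +1.9 uS; positive +5 ms IBI, +2.1 breaths/min,
+3.4 uS), reproducing the ordering and magnitude of group-level autonomic
responses to arousing positive and negative film clips.

### Ratings

Ratings are emitted from latent Gaussians, rounded and clipped to their
Likert bounds: 9-point valence and arousal per member and video; four
7-point connectedness items per member and video (averaged); one 7-point
identification item and seven desire-for-interaction items at the start
(t0) and end (t1) of the session. Latent connectedness rises with centred
latent arousal under joint attention (default slope 0.6 scale points per
arousal point; 0 under disjoint attention), and t1 attitudes rise with
the member's mean connectedness (gain 0.4). All latent values and
coefficients are retained for recovery tests. What the generator does
*not* emulate: facial expression, gaze, ordinal response styles
(acquiescence, central tendency), non-stationary artifacts such as
movement, and real HRV spectra (respiratory sinus arrhythmia is not
explicitly coupled to the respiratory phase). Passing tests therefore
demonstrate correctness of the estimators under the stated statistical
structure, not robustness to every property of real recordings.

## Preprocessing

All filtering is Butterworth, applied forward–backward (zero phase) so
that peak timing is preserved across channels; the effective magnitude
order doubles. Odd-reflection padding of six time constants of the low
cutoff suppresses start-up transients (without it, a first-order 0.05 Hz
high-pass leaves multi-uS edge artifacts on a 5-min SC record). The
chains: ECG 1–100 Hz (order 4); interpolated IBI 0.04–0.4 Hz (order 4);
phasic SC 0.05–5 Hz (order 1).

**R-peak detection** builds a QRS template as the median 160 ms beat
around the strongest local maxima (up to 30 beats), cross-correlates it
with the ECG, z-scores the correlation, and accepts local maxima above
0.6 SD with a 250 ms refractory period (a physiological upper bound of
240 bpm). Two deterministic choices replace the interactive visual
correction a human operator would perform: candidates weaker than 40% of
the upper-decile correlation amplitude are rejected (noise crossings of
the 0.6 SD threshold outnumber true beats at low signal-to-noise, so the
reference must come from the strong end of the distribution), and each
accepted peak is refined to the local ECG maximum within ±20 ms. On
synthetic ECG this yields perfect sensitivity/precision at 10 dB peak
SNR and sub-millisecond timing when noiseless.

**IBI series**: intervals in ms between consecutive peaks; cubic-spline
interpolation resampled at 20 Hz on `[first_peak, last_peak]`; mean IBI
recorded before the 0.04–0.4 Hz band-pass. **Expiration onsets**: local
maxima above the signal mean with a 1 s minimum separation. **SCRs**:
upward crossings of a 0.01 uS phasic threshold, 1 s apart.

**Artifact rules.** Respiration: a participant is excluded when the
longest run of null samples exceeds 5% of a video's duration, or when a
recording's variance exceeds the sample mean of variances by three sample
SDs for at least one video. The variance rule's units are ambiguous in
prose ("variance exceeded three times the standard deviation above the
mean"); the default compares variances in variance units, and
`variance_rule = "sd"` switches to SD units. Skin conductance: exclusion
when no SCR is detected in *all three* videos, or when slopes above
2 uS/s in magnitude (evaluated on 1 s windows; the field's usual time
base for this heuristic) cover more than 5% of at least one video.
Statistical outliers: below `Q1 - 3 IQR` or above `Q3 + 3 IQR`, with
type-7 (linear interpolation) quartiles — the most common convention; for
normal data these fences sit near ±4.7 SD, so the rule is near-silent on
clean data. Recordings shorter than 30 s (respiration) or 5 s (ECG) are
rejected with explicit errors rather than silently processed.

## Wavelet transform coherence

For signals `x`, `y` with Morlet transforms `Wx`, `Wy` (centre frequency
`omega0 = 6`, 12 voices per octave, smallest scale `2/fs`, largest scale
a quarter of the record, zero-padding to the next power of two), the
magnitude-squared coherence is

  `R^2 = |S(Wx Wy* / s)|^2 / ( S(|Wx|^2 / s) * S(|Wy|^2 / s) )`,

where `S` smooths with a Gaussian in time (SD `s / sqrt(2)`, applied in
the frequency domain) followed by a boxcar over 0.6 octaves in scale —
the smoothing that makes coherence a local correlation rather than
identically 1. The implementation keeps the scale boxcar at 0.6 octaves
(the convention of the procedure this measure follows); self-coherence
and all bounded-ness properties are insensitive to that width. Values
are clamped to `[0, 1]` against floating-point overshoot. Cells within
`sqrt(2) * scale` of either record edge are inside the cone of
influence and excluded from every average. Scalars are obtained by
averaging usable cells over a frequency band: LF 0.05–0.15 Hz and
HF 0.15–0.4 Hz for cardiac IBI, or the full map range. The
magnitude-squared form is the default; `sqrt_coherence = TRUE` reports
its square root (an absolute-correlation-style value) for comparability
with conventions that average the root.

Two numerical facts matter when interpreting averages. First, smoothing
leaves a positive bias: independent white-noise pairs average ~0.4, not
0, under the default configuration — comparisons must therefore be made
against a matched baseline (the surrogate pool), never against zero.
Second, full-map averages over a 20 Hz IBI trace include frequencies far
above the signal band, which dilutes coupling effects; band-restricted
averages (e.g. 0.04–0.4 Hz) are the sensitive statistic.

The **surrogate-dyad null** pairs every individual with every individual
from a *different* dyad (same attention condition and video), giving
`2m(m-1)` surrogate pairs for `m` dyads. The statistic is
`mean(real) - mean(surrogate)`; its null distribution is built by
resampling `m` values with replacement from the surrogate pool, and the
two-sided p-value uses the add-one correction. Surrogate pair values
share individuals and are therefore mildly dependent; the calibration
test shows the achieved level stays within [1%, 10%] at a nominal 5%.
Per-individual wavelet transforms and smoothed auto-spectra are cached,
so the all-pairs computation costs one cross-smoothing per pair.

## Dyad-level indices and models

Dyadic mean `(a+b)/2` (emotional intensity), absolute difference
`|a-b|` (dissimilarity), mutual product `a*b` (for a fixed sum, maximal
when members agree — intensity *and* reciprocity), and t1−t0 change
scores of mutual products. Multi-item scales are averaged within members
*before* multiplying. Missing members yield missing indices; dyads are
dropped listwise per video, never imputed. `neutral_baseline_correct`
subtracts each dyad's neutral-video row from its positive- and
negative-video rows, yielding two rows per complete dyad.

Models are linear mixed-effects regressions (`lme4`, identity link) with
treatment-coded categorical predictors and z-scored continuous
predictors. Reported fits use REML; model comparison uses ML. Coefficient
p-values use Satterthwaite degrees of freedom (`lmerTest`); selection
decisions use likelihood-ratio tests, which are authoritative here.
`backward_stepwise` ranks candidate fixed effects by single-term LRT
contribution; if the full model fails to converge it simplifies random
slopes first, then the least-contributing fixed terms; it then drops the
term with the largest removal-LRT p-value until every remaining term is
significant at `alpha_keep = 0.05` (two-sided), respecting marginality (a
main effect never leaves while its interaction remains). Singular fits
are flagged, never hidden. The reported `R^2` values follow the
fixed/random variance decomposition (`marginal <= conditional`), and
`ICC = tau00 / (tau00 + sigma^2)` for the single-intercept case.
Likert responses are modelled as continuous throughout: the headline
dyad-level indices (products and means of item averages) are effectively
continuous, and ordinal link functions are out of scope for this
package.

Post hoc tests are nonparametric (Spearman correlations,
Wilcoxon–Mann–Whitney with midranks), with effect sizes reported as
Pearson's r from the normal approximation and Holm's step-down
adjustment across the declared family.

## Problem sizes used by the test suite

The statistical checks run at desk scale, with these sizes:

* Self-coherence and null-bias checks: 300 s traces at 20 Hz; the
  null-bias oracle uses 200 independent white-noise pairs.
* Coupling recovery: coupling grid {0, 0.3, 0.6, 0.9}, 20 dyads per
  level, three 300 s epochs per dyad, averaged over 0.04–0.4 Hz. The
  three-epoch average mirrors the three-video session structure and is
  what makes the small 0 → 0.3 step (driver correlation 0.155) reliably
  detectable.
* Surrogate calibration: 6 dyads of 120 s traces, 6 voices per octave,
  100 simulations of 200 bootstraps.
* Mixed-model recovery: 100 simulations of 50 groups x 6 observations;
  stepwise retention: 60 simulations at 40 dyads x 2 rows (two true
  standardized effects of 0.5 among six candidates) and 40 all-noise
  simulations at n = 200.

## Known limitations

* The WTC smoothing bias depends on the configuration; synchrony values
  are comparable only within one configuration.
* The surrogate bootstrap treats pool draws as exchangeable although
  pairs share individuals; at the tested sizes the level distortion is
  within the stated band, but very small pools (3–4 dyads) will be less
  well calibrated.
* The backward-stepwise procedure inherits the usual post-selection
  caveats: p-values of retained terms are conditional on selection.
* The generator's ratings are conditionally Gaussian before rounding;
  severe floor/ceiling regimes (latent means outside the scale) will
  compress recovered effects.
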