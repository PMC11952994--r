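---
title: "Vocal biomarkers of bronchoconstriction: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vocal biomarkers of bronchoconstriction: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vocalmct)
```

## The problem

During a methacholine challenge test (MCT), inhaled methacholine progressively
narrows the airways of hyperreactive subjects, and the narrowing is quantified
by spirometry as a falling FEV1 (forced expiratory volume in one second).
Airway narrowing also changes how breath sounds and voiced sounds resonate
through the respiratory tract. `vocalmct` implements the analysis chain that
asks: *do acoustic summaries of a standardized respiratory task, recorded on a
phone at each challenge step, track the subject's FEV1 trace?*

The chain is: event labels → quality gate → segmentation and grouping →
resonance enhancement → 40 acoustic parameters per event → 80 μ/σ biomarkers
per sound type → per-subject Pearson screening against FEV1 → best-biomarker
report. A protocol simulator and a synthetic-audio generator close the loop so
every stage can be validated without clinical recordings.

## The respiratory task and its biomarkers

Each recording holds one performance of the task: three cycles of deep
inhalation and exhalation, then a sustained "A" vowel held as long as
possible. Events are marked by half-open time labels `[start, end)`; the
sample at an interval boundary belongs to the following event only (sample
index of time $t$ is $\lfloor t \cdot f_s \rfloor$), so adjacent labels never
double-count samples.

Per event, 40 parameters are computed (ids follow `parameter_table()`):

* **1–2, timing.** Event duration (s); the repetition rate of the event type
  (bpm, from mean inter-onset intervals) or, for the vowel, the fundamental
  frequency (Hz) by autocorrelation with parabolic interpolation and an
  octave-correction step that prefers the smallest lag whose normalised
  autocorrelation is within 90% of the winning peak.
* **3–9, spectral shape.** Centroid, spread, energy (area), flatness
  (geometric/arithmetic mean ratio), roll-off-80, slope (least-squares slope
  of intensity against frequency) and exponent (least-squares slope in
  log-log coordinates).
* **10–23, LPC 1–14.** Autocorrelation-method linear prediction via the
  Levinson-Durbin recursion, predictor convention
  $\hat x[n] = \sum_k a_k x[n-k]$.
* **24–40, MFCC 1–17.** 26 triangular filters equally spaced on the HTK mel
  scale over 0..Nyquist, log filter energies, orthonormal DCT-II; the 0th
  coefficient (overall level) is excluded, which makes the set exactly
  invariant to uniform waveform scaling.

Respiratory events are summarised once per event from a Welch-averaged power
spectrum (2048-sample Hann frames, 50% hop); the vowel is analysed
frame-by-frame over the phonation time. Per sound type, each parameter's pool
(three repetitions, or the vowel frames) is reduced to its mean μ_n and its
population standard deviation σ_n — 80 biomarkers. With three repetitions the
sample/population choice is a coin toss; population is used because the three
repetitions are the complete pool of the step, and the choice is configurable
in spirit by post-scaling (σ is reported, not tested against).

Undefined features — silent frames, unvoiced frames, constant signals — are
carried as explicit missing values and excluded from the μ/σ pools per
parameter, never silently zeroed.

## Intensity, enhancement, and which spectrum feeds which feature

"Intensity" is the squared magnitude of the windowed Fourier transform
(power; a magnitude option exists in `feature_config()`). Before shape
features are measured, the spectrum is passed through a resonance-enhancing
per-bin power-law compression $S \mapsto S^\gamma$ with $\gamma = 0.5$ by
default. Compression raises weak resonances relative to dominant ones while
preserving the rank order of bins — the intent is to recover lower-airway
resonances that arrive at the microphone strongly attenuated.

Routing is deliberate: centroid, spread, flatness and roll-off are computed on
the *enhanced* spectrum (they describe where resonant mass sits); energy and
slope on the *raw* spectrum (they are physical-scale quantities, and this
keeps the natural scaling — energy and slope scale with the squared waveform
amplitude, while all shape features are scale-invariant); the log-log exponent
on the raw spectrum (on the enhanced one it would just be γ times the physical
exponent). LPC works on the raw waveform and MFCC on the raw power spectrum,
since the compression has no defined waveform counterpart.

Numerical guards: the flatness geometric mean floors bins below $10^{-12}$ of
the spectral maximum (silence padding would otherwise zero the statistic);
the LPC normal equations get a relative white-noise loading of $10^{-9}$ on
lag 0, without which strictly band-limited signals make the Toeplitz system
numerically singular; mel filter energies are floored at $10^{-30}$ of their
maximum before the log.

## Quality gate

There is no canonical quality evaluator for phone-recorded breath tasks, so
the gate here is explicit and conventional, with all thresholds configurable
(`quality_thresholds()`): clipped-sample fraction (|x| ≥ 0.999 full scale)
above 1% fails ("clipped"); labeled-event vs unlabeled-gap SNR below 5 dB
fails ("noisy"); any labeled event shorter than 0.2 s fails ("interrupted");
recordings with no labels or essentially zero signal fail outright. Rejection
is per recording — files, not events, are discarded — and every rejection is
logged with its reasons.

## Challenge protocol and PD20

The simulator follows the dosimeter protocol: a saline step (test
discontinued if FEV1 already falls 20%), then cumulative doses 100, 200, 400,
800, 1600 mcg, stopping at the first fall reaching 20%. "Doubling dose" is
read as doubling *cumulative* dose — the only reading consistent with a
1600 mcg cumulative cap. PD20 is the log-linearly interpolated cumulative
dose at the 20% fall,

$$\mathrm{PD20} = \exp\!\left(\ln D_1 + (\ln D_2 - \ln D_1)
\frac{20 - R_1}{R_2 - R_1}\right),$$

with $(D_1, R_1)$ the last step below threshold and $(D_2, R_2)$ the first at
or above it; if the very first dose already reaches 20% there is no left
bracket and PD20 is that dose. A PD20 of at most 800 mcg classifies the test
positive. The stopping comparison uses ≥ so that a fall of exactly 20%
both stops the test and defines PD20 = D, keeping the boundary coherent.

## Correlation screening

Per subject, each of the 80 biomarker traces across challenge steps is
correlated with the FEV1 trace (Pearson). Sex, age and anatomy shift absolute
feature values between subjects, so only *intra-subject* correlation is
meaningful, and the absolute value |ρ| is used — a biomarker falling with
FEV1 and one rising with it are equally informative. p-values come from the
two-sided t-transform with n − 2 degrees of freedom. Missing steps are
handled pairwise-complete with a minimum of 3 steps; constant traces are
skipped. No multiple-testing correction is applied to the ranking (the
screening is exploratory); a Bonferroni column is emitted alongside for
transparency. Best-biomarker ties break deterministically: higher |ρ|, then
μ before σ, then lower parameter id. Cross-subject feature summaries use the
sample standard deviation, treating the cohort as a sample of subjects.

## The synthetic-data generator

Clinical challenge recordings are rarely shareable, so the generator stands
in for them. It emulates, per subject: a Hill-type dose-response
$\mathrm{fall}(d) = F_{max} d^h / (d^h + d_{50}^h)$ with $F_{max} = 40\%$,
$h = 2$ and $d_{50}$ calibrated so the noise-free fall is exactly 20% at the
subject's latent PD20 (non-reactive subjects use a shallow curve capped below
10%); optional Gaussian FEV1 measurement noise; and per step one recording of
the full task with exact labels. Cohort draws follow a realistic adult
MCT-referral cohort: baseline FEV1 ~ Normal(3.40, 0.79) L truncated above 1 L, reactive
fraction 0.325, latent PD20 ~ Normal(530.77, 264.24) mcg truncated to
[25, 800].

Audio is source-filter synthesis at 44.1 kHz. Exhalations (and inhalations)
are band-limited Gaussian noise (100–6000 Hz) through a single two-pole
resonator; vowels are an impulse train at f0 through a cascade of three
formant resonators (800/1200/2600 Hz, an "A") plus weak aspiration noise.
The coupling ties one synthesis control to the step's FEV1 ratio: by default
the exhalation resonance center, $f_c = 1400 + 1200\,(1 - \mathrm{FEV1}/
\mathrm{baseline})$ Hz — airway narrowing shifting breath-sound resonances
upward, with a magnitude (hundreds of Hz across a 20–35% FEV1 fall) chosen so
the shift is large against spectral-estimation noise but small against the
analysis band. Spectral-tilt and vowel-f0 couplings are available
alternatives. This coupling is a test harness for the pipeline, not a
physiological claim: it produces the *structure* the method is meant to
detect (a monotone acoustic correlate of FEV1), not faithful airway
acoustics.

**Frozen excitation.** By default each subject re-uses the same excitation
noise realisation for repetition k of every step (`excitation = "frozen"` in
`synthesis_config()`), while the recording noise floor (−80 dBFS) is drawn
fresh per recording. The idealisation is that of a reproducible personal
breath gesture: it makes the FEV1 coupling the dominant source of inter-step
acoustic variation, so recovery of the coupled biomarker is a property of the
pipeline rather than of excitation luck, while the fresh noise floor keeps
uncoupled traces fluctuating — with the coupling gain at zero the screening
sees only noise and the coupled biomarker's |ρ| collapses to the null range.
With `excitation = "fresh"` every step re-draws the excitation, adding
realistic attempt-to-attempt variability; under that regime many high-|ρ|
features (roll-off, MFCCs) race the centroid within estimation noise — the
regime in which each subject surfaces a "personal" best feature rather than
one feature dominating the cohort.

What passing synthetic tests does **not** show: that real bronchoconstriction
produces resonance shifts of this form or size, that phone microphones behave
like the ideal mono channel assumed here, or that manual labels are as exact
as the emitted ones. The generator validates the machinery, not the
physiology.

## Problem sizes and reproducibility

All randomness flows from explicit integer seeds (per-subject seeds derived
from a master seed, kept below $2^{31}$); identical seeds give bit-identical
cohorts, tables and reports. The test suite validates feature definitions
against brute-force oracles on random spectra and frames, protocol constants
against the dosimeter schedule, and end-to-end recovery on a 10-subject
cohort at the full 44.1 kHz default configuration (six non-reactive subjects
plus four reactive ones with latent PD20 between 450 and 800 mcg, so every
session executes at least five steps); faster structural checks run on a
16 kHz short-event configuration. These sizes keep the complete validation
run comfortably within a few minutes on one core while exercising every
stage at the nominal smartphone sampling rate.

## Known limitations

* Resonance enhancement is realised as power-law compression; it captures
  the intent (de-penalising weak harmonics, order-preserving) but other
  realisations of the same idea exist and may differ in detail.
* The quality thresholds are conventional heuristics, not validated clinical
  criteria; tune them to the recording setup at hand.
* Breathing-rate estimates need at least two same-type events; a single
  event yields a missing rate, not an error row.
* The vowel's frame-wise duration parameter is the constant frame length, so
  its σ is zero by construction — it carries information only through μ for
  respiratory events.
* WAV support covers mono/multi-channel PCM16 and float32; compressed phone
  formats (AAC/MP3) are out of scope.
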