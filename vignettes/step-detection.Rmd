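---
title: "Template-matched step detection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template-matched step detection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stepmatch)
```

## The problem

Short (about 5 m) walks are the gait assessment that fits a clinic: little
space, little time, feasible for frail patients. Body-fixed accelerometers
make them cheap to instrument — one sensor at the lowest lumbar vertebra
(L5), or one on each heel — but leave the analysis problem of locating every
heel strike in a signal that offers only a handful of gait cycles, too few
for wavelet or long-run spectral methods, and too variable between subjects
for fixed peak heuristics.

`stepmatch` implements a template-match detector for this setting. Instead
of looking for a fixed signal feature at the moment of heel strike, it
estimates each episode's own typical cycle waveform — the *template* — and
then finds the periods of the signal that best match that template in shape
and amplitude. Step (or stride) durations are the intervals between the
matched positions. The detector operates on the anterior-posterior (AP)
acceleration axis only, sampled at 100 samples/s in the intended hardware.

## The detection pipeline

Given a manually segmented stretch of the raw AP signal (from some samples
before the first heel strike to some samples after the last one of
interest), the pipeline runs five stages.

**1. Template length (TL).** The unbiased autocovariance of the segment
(lag k value $\frac{1}{n-k}\sum_t (x_t-\bar x)(x_{t+k}-\bar x)$, positive
lags) carries the periodicity. For the lower back the cycle is one *step*:
TL = `round(fs / f_dom)`, where the dominant frequency $f_{dom}$ is the
argmax of the magnitude spectrum of the positive-lag autocovariance within
a physiologic band (0.3–5 Hz by default, on a 0.01 Hz zero-padded FFT
grid). For a heel the cycle is one *stride*: the autocovariance is
normalized by its lag-0 value, low-pass filtered at twice the dominant
frequency (zero-phase Butterworth of order 2), and TL is the lag between
the first two local maxima exceeding 0.5, with lag 0 counting as the first
peak. Because the unbiased normalization amplifies the noisy long-lag tail,
only lags up to half the segment length enter either rule; and because the
autocovariance is an even function of the lag, the filter is applied to its
mirrored extension so the lag-0 peak is not destroyed by filter edge
transients.

**2. Template construction.** Local maxima of the segment, at least
115 % TL from both segment ends and at least 40 % TL apart, anchor one
*section* each: from 15 % TL before the peak (5 % TL for heels, whose
impact peaks rise more steeply) to 100 % TL after it. Consecutive sections
are averaged pairwise along their dynamic-time-warping alignment path
(absolute-difference cost, steps {(1,0),(0,1),(1,1)}, pinned endpoints),
the averaged sequence resampled back to the section length; the list halves
each round until a single average remains, which is reduced to exactly TL
samples. Averaging along the DTW path, rather than pointwise, is what lets
a handful of cycles with timing jitter produce a clean template.

**3. Resegmentation.** The segment is extended by TL samples to the left
and twice TL to the right out of the raw recording, so the sliding window
can cover the first and last cycles completely.

**4. Match signals.** A TL-sample window slides along the resegmented
signal. Two profiles are computed per window start: the population standard
deviation of the pointwise window-template difference (*SD difference
signal*, low where shape and amplitude match), and the Pearson correlation
multiplied by a symmetric range-ratio factor $\min(\rho, 1/\rho)$ with
$\rho$ the window-to-template amplitude-range ratio (*correlation signal*,
high at matches). Both are normalized by their maxima; their ratio is the
*coefficient signal*, whose peaks mark cycle starts. An $\varepsilon$-floor
(1e-3) on the normalized SD keeps a near-perfect match from dividing by
zero.

**5. Events.** Coefficient local maxima are admitted greedily in descending
value under a minimum spacing of 60 % TL, then kept only if the window
start lies within the span of the original segment (widened on the left by
the forward shift below). Running the spacing suppression *before* the
segment filter matters: the strong matches of the cycles just outside the
segment shield its edges from small spurious maxima. Selected window starts
are shifted forward by 15 % TL (5 % for heels) — undoing the pre-peak
margin of step 2 — to approximate the heel-strike instants. Intervals
between events are step durations (lower back) or stride durations (single
heel); merging the two heels' events, which must alternate feet, yields
step durations again.

## The reference method and the comparison statistics

The optical reference resamples marker trajectories from 200 to
100 samples/s (plain decimation, which preserves measured positions; a
target sample's visibility requires all source samples visible). Around
each heel-acceleration event a 40-sample window is checked for continuous
visibility; per body site the marker with the most complete windows is
selected; and within each complete window the heel strike is the sample
maximising the AP distance between the heel and lower-back markers — the
heel is farthest in front of the trunk exactly at touch-down. Incomplete
windows yield *missed* reference events.

Method comparison matches events by order. Where the reference missed an
event, the two adjacent step comparisons are replaced by the single stride
comparison spanning the gap (both of the adjacent steps are undefined on
the reference side, but their sum is not). Agreement is summarised by the
per-pair absolute differences (mean, SD, and the mean as a percentage of
the pooled mean step duration, stride entries contributing half their
value), the two-way random-effects absolute-agreement single-measures
intraclass correlation ICC(2,1) computed from the ANOVA mean squares, and a
normality-gated paired test: Shapiro–Wilk on the paired differences, then a
paired t-test if normality is not rejected at $\alpha = 0.05$, a Wilcoxon
signed-rank test otherwise.

## The synthetic generator

No recordings ship with the package; every stage is exercised on synthetic
trials with known ground truth (`generate_trial()`). The generator is a
parametric idealization of gait signals, not a biomechanical simulation:
its purpose is to encode event *timing* exactly while looking enough like
gait for the detector's assumptions to be meaningfully stressed.

* **Timing.** Per-step durations are drawn from a normal distribution
  truncated at ±3 SD (mean 560 ms — a typical preferred-pace value for
  healthy older adults — SD `step_cv * mean`), with left- and right-led
  steps offset by ±`asymmetry/2`. Ground truth is the resulting
  heel-strike sample indices; an episode of `n_steps` steps has
  `n_steps + 1` of them. Three lead-in and three lead-out strikes are
  synthesized beyond the reported episode so the signals behave like an
  excerpt of ongoing gait; the default segmentation opens 0.6 steps before
  the first reported strike and closes a quarter step after the last.
* **Lower back.** One asymmetric biphasic pulse per heel strike (sharp
  positive impact lobe exactly on the strike sample, smaller leading and
  trailing negative lobes, about 30 % of a step wide, ±10 % amplitude by
  side), a trunk-sway fundamental at the step frequency and a low-amplitude
  second harmonic, both phased so the stretch between pulses decays
  monotonically before the pre-strike rise — real trunk acceleration has no
  flat quiet phase, and a monotone inter-pulse course means the clean
  waveform has no secondary mid-step maxima.
* **Heels.** Per own-foot strike: a high, sharp impact spike (maximum on
  the strike sample, rise below 30 ms), a damped post-impact oscillation, a
  broad stance/push-off bump, and a stride-frequency sway component. The
  broad components carry most of the cycle energy, which is what makes the
  stride periodicity survive the low-pass filter in the heel TL rule.
* **Markers.** Heel markers advance in stride cycles whose anterior extreme
  relative to a smoothly advancing lower-back marker falls exactly on each
  own-foot strike, sampled at 200 samples/s with sub-0.1 mm position noise.
  Three candidates per heel carry increasing dropout rates (the alternates
  clearly worse, so marker selection is deterministic and the realized
  missed-interval rate tracks the calibrated one); `dropout_for_missed()`
  inverts the visibility model to hit a target incomplete-interval
  fraction. Lower-back cluster markers are always visible.
* **Noise.** Additive white Gaussian noise per trace, either as an SD
  relative to the waveform peak (`noise_sd`) or calibrated to a stated
  in-segment signal-to-noise ratio (`snr_db`).

All randomness flows from the single `seed`; identical parameters give
byte-identical trials.

What passing tests on these trials shows — and what it does not: the suite
demonstrates that the detector recovers known event timing through
realistic levels of timing variability, asymmetry and broadband noise, that
the two sensor placements agree, and that the reference and comparison
machinery behave as specified. It cannot certify performance on real
recordings, whose waveform shape varies between subjects and within an
episode (gait initiation and termination especially) in ways the stereotyped
pulses do not reproduce.

## Numerical and design choices

* **Rounding.** Every "% of TL" quantity becomes an integer sample count by
  rounding half away from zero, with a floor of one sample.
* **Indices.** Sample indices are 1-based and windows closed (`[start,
  end]`, length `end − start + 1`), the natural R convention; all length
  arithmetic (section length `round(pre·TL) + TL`, match-signal length
  `n − TL + 1`, resegmentation `±TL/2TL`) is unchanged by the convention.
* **Anchor height floor.** Anchor-peak candidates must reach, above the
  segment median, at least half the height of the tallest candidate
  (`peak_min_height_frac`, settable to 0). Without a floor, any local
  maximum at least 40 % TL from the admitted peaks is adopted as a section
  anchor — and in a noisy signal the stretch between cycles always contains
  such maxima, regardless of how small they are. Sections anchored on them
  are phase-shifted copies of the cycle; DTW averaging then drags the
  template anchor far off the impact peak (we measured displacements up to
  ~70 samples at 10 dB SNR), which shifts every event by a per-sensor
  constant and breaks the agreement between feet. Impact peaks are several
  times taller than inter-cycle maxima, so a relative floor removes the
  failure mode without touching the clean-signal behaviour. The floor is
  measured from the segment median so that admission is invariant to
  constant offsets and positive gain. Event-peak selection (stage 5) keeps
  the floor-free greedy rule.
* **Amplitude canonicalization.** Before detection, a trace is standardized
  to a robust location/scale taken from the segment (single order
  statistics) and quantized at $2^{-12}$ of that scale — below the 1 mg
  resolution of the target sensors. Detection decisions then operate on
  bit-identical values for any input related by offset or positive gain,
  making event indices *exactly* invariant under such transforms (DTW cost
  ties would otherwise resolve differently under floating-point rescaling).
* **Template fit.** Sections are `round(pre·TL) + TL` samples long but the
  template has TL samples. The default keeps the first TL samples of the
  final average (one full cycle beginning at the sliding-window origin,
  so the window start maps onto the heel strike through the forward shift
  exactly); linear warping of the whole section onto TL samples is
  available as `template_fit = "resample"`.
* **Range ratio.** The correlation signal's amplitude factor is the
  symmetric per-window `min(ρ, 1/ρ)` by default; the raw per-window ratio
  and a global (no-op) variant are selectable, since a global ratio is
  absorbed by the final normalization.
* **Dominant frequency.** Extracted as a spectral argmax over a physiologic
  band with a periodicity floor: the lag-normalized autocovariance must
  exceed `min_periodicity` (0.3) somewhere beyond one shortest in-band
  period, otherwise the signal is declared aperiodic (constant signals and
  white noise fail here, with a clear error).
* **Ties.** Greedy selections break height ties at the earlier index; the
  DTW backtrack prefers the diagonal step; argmax ties in the marker rule
  take the earliest sample.
* **Degenerate inputs.** Constant traces, windows, or templates raise
  classed errors (`stepmatch_degenerate_signal`, `stepmatch_degenerate_match`)
  tagged with the pipeline stage that failed; a single detected event (no
  duration), non-alternating heel events, and unresolvable event pairings
  are errors rather than silent results.

## Problem sizes

The bundled verification suites run 200 synthetic trials of 8–12 steps per
condition (noiseless and 10 dB SNR) for the completeness and timing checks,
100-replicate oracle sweeps for the sliding signals and autocovariance,
exhaustive DTW path enumeration up to length 8, and 1000 replicates for the
normality-gate calibration; the whole test suite completes in under two
minutes on one CPU. The acceptance script reruns the main computations at
100 trials per condition.

## Known limitations

* The detector is defined for straight, steady walking excerpts; gait
  initiation, turning and stopping are outside its scope, and the first
  detected event of a real episode is expected to be the least accurate.
* Events are integer sample indices; at 100 samples/s the temporal
  resolution (10 ms) is a substantial fraction of the achievable accuracy.
* The lower-back method does not label steps left or right.
* Heel-strike timing from the two heels relies on each foot's template
  being anchored at the same cycle phase; between-sensor differences in
  waveform shape (loose attachment, different shoes) degrade step durations
  from combined heels before they degrade per-foot stride durations.
* The synthetic generator's waveforms are stereotyped; results on it bound
  algorithmic, not physiological, sources of error.
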