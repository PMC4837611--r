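# stepmatch

Heel-strike detection and step/stride duration estimation from short
(≈5 m) episodes of gait, using anterior-posterior (AP) acceleration
recorded at the lower back (L5) or at both heels — the settings of a
typical clinical gait assessment of older adults, where only a handful of
gait cycles are available and fixed peak heuristics or wavelet methods
struggle.

## The method

The detector is a per-episode template match. For a manually segmented
signal `x` at sampling rate `fs`:

1. **Template length.** The unbiased autocovariance
   `c(k) = (1/(n−k)) Σ (x_t − x̄)(x_{t+k} − x̄)` carries the gait
   periodicity. For the lower back (step-periodic) the template length is
   `TL = round(fs / f_dom)`, with `f_dom` the spectral argmax of the
   positive-lag autocovariance in 0.3–5 Hz. For a heel (stride-periodic)
   TL is the lag between the first two peaks above 0.5 of the normalized,
   low-pass-filtered (cutoff `2·f_dom`) autocovariance, lag 0 counting as
   the first peak.
2. **Template.** Signal sections anchored at amplitude peaks (≥ 40 % TL
   apart, within limits 115 % TL from the segment ends), each starting
   15 % TL before its peak (5 % for heels) and ending 100 % TL after, are
   reduced to a single average by pairwise dynamic-time-warping alignment
   and averaging, then cut to TL samples.
3. **Matching.** A TL-sample window slides over the segment extended by TL
   left and 2 TL right. The *coefficient signal* is the ratio of the
   normalized sliding correlation (times the symmetric range ratio
   `min(ρ, 1/ρ)`) to the normalized sliding SD of the window−template
   difference; its peaks, at least 60 % TL apart and within the original
   segment, shifted forward by 15 % TL (5 % heel), are the heel-strike
   events. Event intervals are step durations (lower back) or stride
   durations (one heel); the merged, alternating events of both heels give
   step durations again.

The optical reference method (visibility-gated maxima of the AP
heel-to-back marker distance around heel-acceleration events), the
between-method agreement statistics (absolute step-duration differences,
ICC(2,1), Shapiro–Wilk-gated paired t / Wilcoxon tests, with a stride
fallback where the reference missed an event), and a synthetic gait
generator with exact ground-truth heel strikes complete the package.

## Worked example

```r
library(stepmatch)

params <- gait_params(n_steps = 10, step_cv = 0.02, asymmetry = 0.03,
                      snr_db = 15, seed = 42)
trial <- generate_trial(params)
trial
#> <gait_trial> 10 steps, 11 ground-truth heel strikes, 1146 samples at 100 Hz
#>   segment [255, 871]; noise SD (lb/hl/hr): 0.0631 / 0.121 / 0.123

lb <- detect_steps_lowback(trial$lowback, trial$window)
lb
#> <step_detection> lower_back: 11 events, TL = 57 samples (1.76 Hz)
#>   mean step duration 568 ms (sd 14.8 ms)
```

Eleven heel strikes were detected from the lower-back trace — exactly the
ground-truth count, each within one sample (10 ms) of the true instant —
using a step-cycle template of 57 samples (cadence 1.76 Hz). The same
trial through the heel pipeline and the optical reference:

```r
heel <- detect_steps_heel(trial$heel_left, trial$heel_right, trial$window)
heel
#> <heel_detection> 11 combined events (5 left + 6 right strides)
#>   mean step duration 568 ms

ref <- marker_reference(trial$markers$heel_left, trial$markers$heel_right,
                        trial$markers$back, heel$events)
ref
#> <reference_detection> 11 events, 0/11 anchors missed (0.0%)

compare_methods(lb$events, ref$events, missed_b = ref$missed)
#> <method_comparison> lowback_accel vs marker_reference, 10 pairs
#>   mean |diff| 4.0 +/- 5.2 ms (0.7% of mean step duration)
#>   ICC(2,1) = 0.897
#>   Wilcoxon signed-rank p = 1 (Shapiro-Wilk p = 0.0219, alpha = 0.05)
```

The two methods disagree by 4 ms per step on average (0.7 % of the mean
step duration) with an ICC(2,1) of 0.90; the gated test used Wilcoxon
because the paired differences failed the Shapiro–Wilk normality check.
`tidy()` and `glance()` return the per-event / per-pair tibbles and one-row
summaries; `ggplot2::autoplot()` plots detections, comparisons and trials.

A thin command-line interface over the same functions is installed at
`inst/cli/stepmatch` (subcommands `simulate`, `detect-lowback`,
`detect-heel`, `reference`, `compare`).

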