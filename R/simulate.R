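#' Parameters of a synthetic gait trial
#'
#' Bundles and validates everything the generator needs. Defaults emulate
#' the study conditions of the detector: 100 samples/s accelerometry,
#' 200 samples/s optical markers, a mean step duration of 560 ms (healthy
#' elderly at preferred speed over 5 m), modest step-duration variability
#' and left/right asymmetry.
#'
#' @param n_steps Number of step durations in the episode (so `n_steps + 1`
#'   ground-truth heel strikes); at least 4.
#' @param mean_step_ms Mean step duration in ms (> 200).
#' @param step_cv Coefficient of variation of step duration (fractional SD,
#'   `0 <= step_cv < 0.2`).
#' @param asymmetry Fractional left/right step-duration offset: left steps
#'   average `mean * (1 + asymmetry/2)`, right steps `mean * (1 - asymmetry/2)`.
#' @param noise_sd Additive Gaussian noise SD relative to the clean waveform
#'   peak (ignored when `snr_db` is given).
#' @param snr_db Optional signal-to-noise ratio in dB; when given, each
#'   trace's noise SD is set so that the clean in-segment signal variance
#'   over the noise variance equals `10^(snr_db/10)`.
#' @param dropout Per-sample probability (at `marker_fs`) that the best heel
#'   marker is invisible; the two alternate heel candidates are markedly
#'   worse (20 and 30 times this rate), and the lower-back (cluster)
#'   markers are always visible.
#' @param marker_noise_mm Optical position noise SD in mm.
#' @param fs Accelerometer sampling rate, samples/s.
#' @param marker_fs Marker sampling rate, samples/s.
#' @param seed Integer seed; every random draw of the trial flows from it.
#' @return A validated list of class `"gait_params"`.
#' @export
gait_params <- function(n_steps = 10, mean_step_ms = 560, step_cv = 0.02,
                        asymmetry = 0.02, noise_sd = 0.05, snr_db = NULL,
                        dropout = 0, marker_noise_mm = 0.02,
                        fs = 100, marker_fs = 200, seed = 1) {
  if (n_steps < 4) abort_stage("n_steps must be at least 4", "stepmatch_invalid_params")
  if (mean_step_ms <= 200) abort_stage("mean_step_ms must exceed 200", "stepmatch_invalid_params")
  if (step_cv < 0 || step_cv >= 0.2) abort_stage("step_cv must be in [0, 0.2)", "stepmatch_invalid_params")
  if (fs <= 0 || marker_fs <= 0) abort_stage("sampling rates must be positive", "stepmatch_invalid_params")
  if (dropout < 0 || dropout > 1) abort_stage("dropout must be in [0, 1]", "stepmatch_invalid_params")
  structure(list(n_steps = as.integer(n_steps), mean_step_ms = mean_step_ms,
                 step_cv = step_cv, asymmetry = asymmetry, noise_sd = noise_sd,
                 snr_db = snr_db, dropout = dropout,
                 marker_noise_mm = marker_noise_mm, fs = fs,
                 marker_fs = marker_fs, seed = as.integer(seed)),
            class = "gait_params")
}

# normal draws truncated at +/- 3 SD (keeps step durations positive and
# realistic), by rejection
rtruncnorm3 <- function(n, mean, sd) {
  if (sd == 0) return(rep_len(mean, n))
  out <- stats::rnorm(n, mean, sd)
  bad <- abs(out - mean) > 3 * sd
  while (any(bad)) {
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- abs(out - mean) > 3 * sd
  }
  out
}

# piecewise-linear step phase: 0, 1, 2, ... at the strike samples, linearly
# extrapolated with the mean step outside
step_phase <- function(t, strikes) {
  mean_step <- mean(diff(strikes))
  stats::approx(strikes, seq_along(strikes) - 1, xout = t, rule = 2)$y +
    ifelse(t < strikes[1], (t - strikes[1]) / mean_step,
           ifelse(t > strikes[length(strikes)],
                  (t - strikes[length(strikes)]) / mean_step, 0))
}

# one stereotyped lower-back step pulse per heel strike: asymmetric biphasic
# (sharp positive impact lobe at the strike, smaller trailing and leading
# negative lobes), about 30 % of a step wide
lowback_clean <- function(n, strikes, sides, mean_step_samples) {
  t <- seq_len(n)
  x <- numeric(n)
  w <- mean_step_samples / 56  # shape scales with cadence
  for (i in seq_along(strikes)) {
    s <- strikes[i]
    amp <- if (sides[i] == "left") 1.1 else 0.9
    idx <- which(t >= s - 12 * w & t <= s + 16 * w)
    d <- t[idx] - s
    x[idx] <- x[idx] + amp * (exp(-0.5 * (d / (2.5 * w))^2)
                              - 0.35 * exp(-0.5 * ((d - 6 * w) / (4 * w))^2)
                              - 0.20 * exp(-0.5 * ((d + 6 * w) / (3.5 * w))^2))
  }
  # trunk sway at the step fundamental plus a low-amplitude harmonic at
  # twice the step frequency; both are phased so the stretch between the
  # impact pulses decays monotonically before the pre-strike rise (no
  # secondary mid-step maxima)
  u <- step_phase(t, strikes)
  x + 0.35 * cos(2 * pi * (u - 0.18)) + 0.08 * cos(4 * pi * (u - 0.385))
}

# stride-periodic heel waveform: sharp high-amplitude impact spike (rise
# under 30 ms), damped post-impact oscillation, and a broad stance/push-off
# bump carrying most of the cycle energy (so the stride periodicity
# survives low-pass filtering of the autocovariance); quiet terminal-swing
# interval before the next spike
heel_clean <- function(n, strikes_side, mean_stride_samples) {
  t <- seq_len(n)
  x <- numeric(n)
  w <- mean_stride_samples / 112
  for (s in strikes_side) {
    idx <- which(t >= s - 10 * w & t <= s + 90 * w)
    d <- t[idx] - s
    spike <- 2.2 * exp(-0.5 * (d / (1.5 * w))^2)
    osc <- ifelse(d > 0, 0.5 * exp(-d / (7 * w)) * sin(2 * pi * d / (11 * w)), 0)
    bump <- 0.8 * exp(-0.5 * ((d - 36 * w) / (12 * w))^2)
    x[idx] <- x[idx] + spike + osc + bump
  }
  # stride-fundamental sway of the foot, phased so the swing-phase stretch
  # decays monotonically until shortly before the next strike
  u <- step_phase(t, strikes_side)
  x + 0.6 * cos(2 * pi * (u - 0.1))
}

#' Synthetic lower-back acceleration waveform
#'
#' Superposition of one stereotyped biphasic step pulse per heel strike
#' (alternating +/-10 % amplitude by side) plus a low-amplitude harmonic at
#' twice the step frequency plus additive Gaussian noise. The main pulse
#' peak falls exactly on the heel-strike sample.
#'
#' @param strikes Heel-strike sample indices (all feet, ascending).
#' @param sides Character vector (`"left"`/`"right"`) matching `strikes`.
#' @param n_samples Length of the trace.
#' @param params A [gait_params()] (supplies `fs` and `mean_step_ms`).
#' @param noise_sd Absolute noise SD in signal units (0 for a noiseless
#'   trace).
#' @return An [accel_trace()] with placement `"lower_back"`.
#' @export
lowback_waveform <- function(strikes, sides, n_samples, params,
                             noise_sd = 0) {
  mss <- params$mean_step_ms * params$fs / 1000
  x <- lowback_clean(n_samples, strikes, sides, mss)
  if (noise_sd > 0) x <- x + stats::rnorm(n_samples, 0, noise_sd)
  accel_trace(x, fs = params$fs, placement = "lower_back")
}

#' Synthetic heel acceleration waveform
#'
#' Per own-side heel strike: a sharp high-amplitude impact spike (rise below
#' 30 ms) with the maximum exactly at the strike sample, a damped
#' post-impact oscillation and a smooth push-off bump; stride-periodic, with
#' additive Gaussian noise.
#'
#' @param strikes_side Heel-strike sample indices of one foot.
#' @param placement `"heel_left"` or `"heel_right"`.
#' @inheritParams lowback_waveform
#' @return An [accel_trace()].
#' @export
heel_waveform <- function(strikes_side, placement, n_samples, params,
                          noise_sd = 0) {
  msts <- 2 * params$mean_step_ms * params$fs / 1000
  x <- heel_clean(n_samples, strikes_side, msts)
  if (noise_sd > 0) x <- x + stats::rnorm(n_samples, 0, noise_sd)
  accel_trace(x, fs = params$fs, placement = placement)
}

# noise SD delivering the requested SNR over the in-segment clean signal
snr_noise_sd <- function(clean_seg, snr_db) {
  sqrt(stats::var(clean_seg) / 10^(snr_db / 10))
}

#' Heel-marker dropout rate for a target missed-interval fraction
#'
#' Inverts the visibility model: with per-sample dropout probability `p` at
#' the marker rate and conservative 2:1 decimation, an interval of `width`
#' samples at the target rate is complete with probability
#' `(1-p)^(2*width)`. Returns the `p` whose expected incomplete-interval
#' fraction equals `target`.
#'
#' @param target Desired fraction of incomplete intervals (e.g. 0.089).
#' @param width Interval width in samples at the accelerometer rate.
#' @param decimation Marker-to-accelerometer rate ratio (default 2).
#' @return Per-sample dropout probability at the marker sampling rate.
#' @export
dropout_for_missed <- function(target, width = 40, decimation = 2) {
  1 - (1 - target)^(1 / (width * decimation))
}

#' Synthetic optical marker trajectories
#'
#' Heel markers advance in stride-long cycles whose anterior extreme
#' relative to a smoothly advancing lower-back marker occurs exactly at each
#' ground-truth heel strike of that foot, so the AP heel-to-back distance is
#' maximal at touch-down. Three candidate markers per heel (increasing
#' dropout rates) and three always-visible lower-back cluster markers are
#' produced at `marker_fs`.
#'
#' @param strikes_left,strikes_right Per-foot heel-strike samples (at the
#'   accelerometer rate, including any lead-in/lead-out strikes so the cycle
#'   phase is defined over the whole trace).
#' @param n_samples Accelerometer-rate trace length to cover.
#' @param params A [gait_params()].
#' @return A list with elements `heel_left`, `heel_right`, `back`, each a
#'   list of 3 [marker_trace()] candidates.
#' @export
marker_trajectories <- function(strikes_left, strikes_right, n_samples, params) {
  fs <- params$fs; mfs <- params$marker_fs
  nm <- floor((n_samples - 1) * mfs / fs) + 1
  tm <- (seq_len(nm) - 1) / mfs            # seconds
  t_in_fs <- tm * fs + 1                   # accelerometer-rate sample scale
  back_ap <- 1000 * tm                     # ~1 m/s forward progression
  noise <- function() stats::rnorm(nm, 0, params$marker_noise_mm)
  heel_ap <- function(strikes_side) {
    u <- step_phase(t_in_fs, strikes_side) # stride phase for one foot
    back_ap + 150 * cos(2 * pi * u)
  }
  mk <- function(ap, site, id, p_drop) {
    vis <- if (p_drop <= 0) rep(TRUE, nm) else stats::runif(nm) >= p_drop
    marker_trace(ap + noise(),
                 ml = 30 * sin(2 * pi * tm) + noise(),
                 vert = 50 + 20 * abs(sin(2 * pi * tm)) + noise(),
                 visible = vis, fs = mfs, site = site, marker_id = id)
  }
  # the two alternate candidates per heel are clearly worse, so the
  # best-visible marker (rate `dropout`) is selected and the realized
  # missed-interval fraction tracks the calibrated rate
  p <- params$dropout
  list(
    heel_left = list(mk(heel_ap(strikes_left), "heel_left", "hl1", min(1, 20 * p)),
                     mk(heel_ap(strikes_left), "heel_left", "hl2", p),
                     mk(heel_ap(strikes_left), "heel_left", "hl3", min(1, 30 * p))),
    heel_right = list(mk(heel_ap(strikes_right), "heel_right", "hr1", min(1, 20 * p)),
                      mk(heel_ap(strikes_right), "heel_right", "hr2", p),
                      mk(heel_ap(strikes_right), "heel_right", "hr3", min(1, 30 * p))),
    back = list(mk(back_ap, "lower_back", "lb1", 0),
                mk(back_ap, "lower_back", "lb2", 0),
                mk(back_ap, "lower_back", "lb3", 0))
  )
}

#' Generate a complete synthetic gait trial
#'
#' Draws per-step durations from a truncated normal (side-specific means
#' under the asymmetry, SD `step_cv * mean`, truncated at +/-3 SD), builds
#' the ground-truth heel-strike sample indices, and synthesizes the
#' lower-back trace, both heel traces and the optical marker candidates,
#' all time-aligned. Three lead-in and three lead-out strikes are simulated
#' beyond the reported episode so the signals behave like an excerpt of
#' ongoing gait; the default segmentation window opens three quarters of a
#' step before the first reported strike and closes a quarter step after
#' the last.
#'
#' @param params A [gait_params()].
#' @return A list of class `"gait_trial"`: `lowback`, `heel_left`,
#'   `heel_right` ([accel_trace()]s), `markers` (see
#'   [marker_trajectories()]), `truth` (tibble `event`, `side`),
#'   `truth_left`, `truth_right` (integer sample indices), `window`
#'   (default [seg_window()]), `noise_sd` (per-trace SDs used), `params`.
#' @export
generate_trial <- function(params = gait_params()) {
  stopifnot(inherits(params, "gait_params"))
  set.seed(params$seed)
  fs <- params$fs
  n_steps <- params$n_steps
  n_internal <- n_steps + 7L            # 3 lead-in + episode + 3 lead-out
  # strike k is "left" for odd k; step k (strike k -> k+1) is led by the
  # foot striking at k+1
  sides <- ifelse(seq_len(n_internal) %% 2 == 1, "left", "right")
  lead <- sides[-1]
  mean_by_lead <- ifelse(lead == "left",
                         params$mean_step_ms * (1 + params$asymmetry / 2),
                         params$mean_step_ms * (1 - params$asymmetry / 2))
  durs_ms <- rtruncnorm3(n_internal - 1L, mean_by_lead,
                         params$step_cv * params$mean_step_ms)
  t_ms <- c(0, cumsum(durs_ms))
  # quiet padding beyond the lead-in/lead-out strikes; generous enough that
  # resegmentation (TL left, 2 TL right of the segment) always fits even
  # when the stride template length overshoots by a few samples
  pad <- 120L
  strikes <- as.integer(round(t_ms * fs / 1000)) + pad + 1L
  n <- strikes[n_internal] + pad
  truth_idx <- 4:(4 + n_steps)
  truth <- tibble::tibble(event = strikes[truth_idx], side = sides[truth_idx])
  mean_step_samples <- params$mean_step_ms * fs / 1000
  window <- seg_window(truth$event[1] - round_half_up(0.6 * mean_step_samples),
                       truth$event[nrow(truth)] + round_half_up(0.25 * mean_step_samples))

  left_all <- strikes[sides == "left"]
  right_all <- strikes[sides == "right"]
  clean_lb <- lowback_clean(n, strikes, sides, mean_step_samples)
  clean_hl <- heel_clean(n, left_all, 2 * mean_step_samples)
  clean_hr <- heel_clean(n, right_all, 2 * mean_step_samples)
  seg <- window$start:window$end
  sd_for <- function(clean) {
    if (!is.null(params$snr_db)) snr_noise_sd(clean[seg], params$snr_db)
    else params$noise_sd * max(abs(clean))
  }
  noisy <- function(clean, sd) {
    if (sd > 0) clean + stats::rnorm(n, 0, sd) else clean
  }
  sds <- c(lowback = sd_for(clean_lb), heel_left = sd_for(clean_hl),
           heel_right = sd_for(clean_hr))
  lowback <- accel_trace(noisy(clean_lb, sds[["lowback"]]), fs, "lower_back")
  heel_left <- accel_trace(noisy(clean_hl, sds[["heel_left"]]), fs, "heel_left")
  heel_right <- accel_trace(noisy(clean_hr, sds[["heel_right"]]), fs, "heel_right")
  markers <- marker_trajectories(left_all, right_all, n, params)

  structure(list(
    lowback = lowback, heel_left = heel_left, heel_right = heel_right,
    markers = markers, truth = truth,
    truth_left = truth$event[truth$side == "left"],
    truth_right = truth$event[truth$side == "right"],
    window = window, noise_sd = sds, params = params
  ), class = "gait_trial")
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf("<gait_trial> %d steps, %d ground-truth heel strikes, %d samples at %g Hz\n",
              x$params$n_steps, nrow(x$truth), nrow(x$lowback), x$params$fs))
  cat(sprintf("  segment [%d, %d]; noise SD (lb/hl/hr): %.3g / %.3g / %.3g\n",
              x$window$start, x$window$end,
              x$noise_sd[1], x$noise_sd[2], x$noise_sd[3]))
  invisible(x)
}
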