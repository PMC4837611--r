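#' Resegment the raw trace around a segment window
#'
#' Extends the manual segmentation by TL samples to the left and twice TL
#' samples to the right, taken from the raw acceleration trace, so that the
#' sliding template window can cover the first and last cycles of the
#' segment completely.
#'
#' @param raw The raw (unsegmented) [accel_trace()].
#' @param window The manual [seg_window()].
#' @param tl Template length (samples) or `"template_length"`.
#' @return A list with `trace` (the resegmented `accel_trace`, raw `sample`
#'   indices retained) and `window` (the extended `seg_window`).
#' @export
resegment <- function(raw, window, tl) {
  tl <- if (inherits(tl, "template_length")) tl$tl else as.integer(tl)
  if (tl < 1) abort_stage("template length must be positive", "stepmatch_invalid_input")
  n <- nrow(raw)
  new_start <- window$start - tl
  new_end <- window$end + 2L * tl
  if (new_start < 1) {
    abort_stage(sprintf(
      "resegmentation needs %d samples left of the segment but only %d exist",
      tl, window$start - 1L), "stepmatch_resegment_error")
  }
  if (new_end > n) {
    abort_stage(sprintf(
      "resegmentation needs %d samples right of the segment but only %d exist",
      2L * tl, n - window$end), "stepmatch_resegment_error")
  }
  new_window <- seg_window(new_start, new_end)
  list(trace = segment_trace(raw, new_window), window = new_window)
}

# embed a signal as a (n-tl+1) x tl matrix of sliding windows
sliding_windows <- function(x, tl) {
  n <- length(x)
  w <- n - tl + 1L
  if (w < 1) {
    abort_stage("signal shorter than the template", "stepmatch_invalid_input")
  }
  matrix(x[outer(seq_len(w), 0:(tl - 1L), `+`)], nrow = w)
}

#' Sliding SD-of-difference signal
#'
#' For each placement of a TL-sample window on the resegmented signal, the
#' population standard deviation (divide by TL) of the pointwise difference
#' between the window and the template, normalized by the maximum over all
#' placements. Minima mark window starts where the signal matches the
#' template in shape and amplitude.
#'
#' @param reseg Resegmented signal (numeric vector or `accel_trace`).
#' @param template A `"template_signal"` or numeric vector.
#' @return Numeric vector of length `length(reseg) - TL + 1`, in `[0, 1]`.
#' @export
sd_difference_signal <- function(reseg, template) {
  x <- if (inherits(reseg, "accel_trace")) reseg$accel else as.double(reseg)
  tv <- if (inherits(template, "template_signal")) template$values else as.double(template)
  tl <- length(tv)
  W <- sliding_windows(x, tl)
  diffs <- sweep(W, 2, tv)
  # population SD of each row
  sds <- sqrt(rowMeans(diffs^2) - rowMeans(diffs)^2)
  sds[sds < 0 | !is.finite(sds)] <- 0
  mx <- max(sds)
  if (mx <= 0) {
    abort_stage("SD-difference signal is identically zero (constant signals)",
                "stepmatch_degenerate_match")
  }
  sds / mx
}

#' Sliding correlation signal
#'
#' For each TL-sample window, the Pearson correlation with the template,
#' multiplied by a range-ratio factor comparing the window's amplitude range
#' to the template's (by default the symmetric `min(rho, 1/rho)`, which
#' penalizes both larger and smaller windows), then normalized by the
#' maximum. Constant windows get a correlation of 0.
#'
#' @inheritParams sd_difference_signal
#' @param range_ratio `"per_window_sym"`, `"per_window_raw"` or `"global"`,
#'   see [detector_config()].
#' @return Numeric vector of length `length(reseg) - TL + 1` with maximum 1.
#' @export
correlation_signal <- function(reseg, template, range_ratio = "per_window_sym") {
  x <- if (inherits(reseg, "accel_trace")) reseg$accel else as.double(reseg)
  tv <- if (inherits(template, "template_signal")) template$values else as.double(template)
  tl <- length(tv)
  t_sd <- stats::sd(tv) * sqrt((tl - 1) / tl)
  if (!is.finite(t_sd) || t_sd <= 0) {
    abort_stage("template is constant; correlation undefined",
                "stepmatch_degenerate_match")
  }
  W <- sliding_windows(x, tl)
  mw <- rowMeans(W)
  sw <- sqrt(rowMeans(W^2) - mw^2)
  cross <- as.vector(W %*% tv) / tl - mw * mean(tv)
  corr <- ifelse(sw > 0, cross / (sw * t_sd), 0)
  corr[!is.finite(corr)] <- 0
  corr <- pmin(pmax(corr, -1), 1)
  t_range <- diff(range(tv))
  w_range <- apply(W, 1, function(r) diff(range(r)))
  rr <- switch(range_ratio,
    per_window_sym = {
      rho <- w_range / t_range
      ifelse(rho > 0, pmin(rho, 1 / rho), 0)
    },
    per_window_raw = w_range / t_range,
    global = rep(1, length(corr))
  )
  out <- corr * rr
  mx <- max(out)
  if (!is.finite(mx) || mx <= 0) {
    abort_stage("correlation signal has no positive maximum",
                "stepmatch_degenerate_match")
  }
  out / mx
}

#' Coefficient signal
#'
#' Ratio of the normalized correlation signal to the normalized
#' SD-difference signal, with an epsilon floor on the denominator so a
#' near-perfect match (SD approximately 0) produces a large finite peak
#' rather than a division blow-up. Its peaks mark cycle starts.
#'
#' @param correlation,sd_difference Equal-length numeric vectors from
#'   [correlation_signal()] and [sd_difference_signal()].
#' @param sd_floor Denominator floor (default 1e-3 of the normalized SD
#'   scale).
#' @return Numeric vector of the same length.
#' @export
coefficient_signal <- function(correlation, sd_difference, sd_floor = 1e-3) {
  if (length(correlation) != length(sd_difference)) {
    abort_stage("correlation and SD-difference signals differ in length",
                "stepmatch_invalid_input")
  }
  correlation / pmax(sd_difference, sd_floor)
}

#' All three sliding match signals as one tibble
#'
#' Convenience wrapper computing [sd_difference_signal()],
#' [correlation_signal()] and [coefficient_signal()] for a resegmented
#' signal, keeping the raw-trace coordinate of each window start.
#'
#' @param reseg Resegmented `accel_trace` (from [resegment()]), its `sample`
#'   column holding raw-trace indices.
#' @param template A `"template_signal"`.
#' @param config A [detector_config()].
#' @return A tibble with columns `window_start` (raw coordinates),
#'   `sd_difference`, `correlation`, `coefficient`.
#' @export
match_signals <- function(reseg, template, config = detector_config()) {
  offset <- if (inherits(reseg, "accel_trace")) reseg$sample[1] else 1L
  sd_sig <- sd_difference_signal(reseg, template)
  corr_sig <- correlation_signal(reseg, template, config$range_ratio)
  coeff <- coefficient_signal(corr_sig, sd_sig, config$sd_floor)
  tibble::tibble(
    window_start = offset + seq_along(coeff) - 1L,
    sd_difference = sd_sig,
    correlation = corr_sig,
    coefficient = coeff
  )
}

#' Select event peaks on the coefficient signal
#'
#' Local maxima of the coefficient signal over the whole resegmented range
#' are admitted greedily in descending value under a minimum pairwise
#' distance of 60 % TL, and the admitted peaks are then kept only if their
#' sliding-window start lies within the span of the original segmented
#' signal (widened to the left by the forward event shift, so that shifted
#' events land inside the segment). Running the distance suppression before
#' the segment filter matters: the strong matches of the gait cycles just
#' outside the segment (the resegmented signal extends beyond it) shield
#' the segment edges from small spurious maxima.
#'
#' @param coeff Coefficient signal (numeric vector).
#' @param tl Template length (samples) or `"template_length"`.
#' @param seg_window The original manual [seg_window()] (raw coordinates).
#' @param offset Raw-trace coordinate of the first sliding-window start
#'   (i.e. the resegmented signal's first sample).
#' @param shift_fraction Forward shift later applied by [shift_events()]
#'   (0.15 lower back, 0.05 heel).
#' @param config A [detector_config()].
#' @return Integer vector of selected window-start positions in raw-trace
#'   coordinates, ascending.
#' @export
select_event_peaks <- function(coeff, tl, seg_window, offset,
                               shift_fraction = 0.15,
                               config = detector_config()) {
  tl <- if (inherits(tl, "template_length")) tl$tl else as.integer(tl)
  shift <- tl_samples(shift_fraction, tl)
  cand <- local_maxima(coeff)
  sel <- greedy_select(cand, coeff[cand], tl_samples(config$event_min_dist_frac, tl))
  pos_raw <- offset + sel - 1L
  keep <- pos_raw >= (seg_window$start - shift) & pos_raw <= seg_window$end
  pos_raw <- pos_raw[keep]
  if (length(pos_raw) == 0) {
    abort_stage("no coefficient peaks inside the segmented signal; no steps found",
                "stepmatch_no_steps")
  }
  pos_raw
}

#' Heel-strike event series
#'
#' A tibble of strictly increasing heel-strike sample indices (raw-trace
#' coordinates) with the producing method and sampling rate attached.
#'
#' @param events Strictly increasing integer sample indices.
#' @param fs Sampling rate in samples/s.
#' @param method One of `"lowback_accel"`, `"heel_accel_left"`,
#'   `"heel_accel_right"`, `"heel_accel_combined"`, `"marker_reference"`.
#' @param foot Optional per-event foot label (`"left"`/`"right"`), used by
#'   combined heel series.
#' @return A tibble of class `"event_series"` with columns `event`,
#'   `time_s` and optionally `foot`.
#' @export
event_series <- function(events, fs,
                         method = c("lowback_accel", "heel_accel_left",
                                    "heel_accel_right", "heel_accel_combined",
                                    "marker_reference"),
                         foot = NULL) {
  method <- match.arg(method)
  events <- as.integer(events)
  if (length(events) > 1 && any(diff(events) <= 0)) {
    abort_stage("event indices must be strictly increasing", "stepmatch_invalid_input")
  }
  out <- tibble::tibble(event = events, time_s = (events - 1) / fs)
  if (!is.null(foot)) out$foot <- foot
  attr(out, "fs") <- fs
  attr(out, "method") <- method
  class(out) <- c("event_series", class(out))
  out
}

#' Shift selected peaks forward to heel-strike events
#'
#' Each selected coefficient peak marks a sliding-window start; the heel
#' strike it represents lies `round(shift_fraction * TL)` samples later
#' (15 % TL for the lower back, 5 % TL for heels), mirroring the offset by
#' which sections start before their anchor peak.
#'
#' @param peaks Ascending window-start positions (raw coordinates) from
#'   [select_event_peaks()].
#' @param tl Template length (samples) or `"template_length"`.
#' @param shift_fraction Forward shift as fraction of TL.
#' @param fs Sampling rate in samples/s.
#' @param method Method tag for the resulting [event_series()].
#' @return An [event_series()].
#' @export
shift_events <- function(peaks, tl, shift_fraction, fs, method = "lowback_accel") {
  tl <- if (inherits(tl, "template_length")) tl$tl else as.integer(tl)
  if (length(peaks) == 0) return(event_series(integer(0), fs, method))
  event_series(as.integer(peaks) + tl_samples(shift_fraction, tl), fs, method)
}

#' Step or stride durations between events
#'
#' Durations are the intervals between consecutive events, in milliseconds:
#' `(event[k+1] - event[k]) * 1000 / fs`.
#'
#' @param ev An [event_series()] with at least 2 events.
#' @param kind `"step"` or `"stride"` label for the produced durations.
#' @return A tibble with columns `duration_ms` and `kind`.
#' @export
durations_from_events <- function(ev, kind = NULL) {
  fs <- attr(ev, "fs")
  if (is.null(kind)) {
    kind <- if (identical(attr(ev, "method"), "heel_accel_left") ||
                identical(attr(ev, "method"), "heel_accel_right")) "stride" else "step"
  }
  if (nrow(ev) < 2) {
    abort_stage("need at least 2 events to compute durations", "stepmatch_invalid_input")
  }
  tibble::tibble(duration_ms = diff(ev$event) * 1000 / fs, kind = kind)
}

#' Combine left and right heel event series into steps
#'
#' Stride events of the two feet are merged in ascending order; consecutive
#' merged events must come from alternating feet (a heel strike of one foot
#' is always followed by one of the other foot), otherwise an interleaving
#' error reports the offending positions. Intervals of the merged series are
#' step durations.
#'
#' @param left,right [event_series()] of the left and right heel.
#' @return An [event_series()] with method `"heel_accel_combined"` and a
#'   `foot` column.
#' @export
combine_heel_events <- function(left, right) {
  fs <- attr(left, "fs")
  ev <- c(left$event, right$event)
  foot <- c(rep("left", nrow(left)), rep("right", nrow(right)))
  ord <- order(ev)
  ev <- ev[ord]; foot <- foot[ord]
  same <- which(diff(match(foot, c("left", "right"))) == 0)
  if (length(same) > 0) {
    abort_stage(sprintf(
      "consecutive merged events %s and %s are both from the %s foot",
      ev[same[1]], ev[same[1] + 1], foot[same[1]]), "stepmatch_interleaving_error")
  }
  event_series(ev, fs, method = "heel_accel_combined", foot = foot)
}
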