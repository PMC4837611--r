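new_step_detection <- function(events, durations, template, tl, match,
                               window, placement) {
  structure(
    list(events = events, durations = durations, template = template,
         tl = tl, match = match, window = window, placement = placement),
    class = "step_detection")
}

#' @export
print.step_detection <- function(x, ...) {
  cat(sprintf("<step_detection> %s: %d events, TL = %d samples (%.2f Hz)\n",
              x$placement, nrow(x$events), x$tl$tl, x$tl$dominant_freq))
  if (nrow(x$durations) > 0) {
    cat(sprintf("  mean %s duration %.0f ms (sd %.1f ms)\n",
                x$durations$kind[1], mean(x$durations$duration_ms),
                stats::sd(x$durations$duration_ms)))
  }
  invisible(x)
}

# Standardize the trace to a robust amplitude scale taken from the segment
# (single order statistics, no averaging) and quantize at 2^-12 of that
# scale, below the resolution of the accelerometers the method targets.
# Detection decisions then operate on bit-identical values for any input
# related by offset or positive gain, making event indices exactly
# invariant under such transforms.
canonicalize_trace <- function(raw, window) {
  srt <- sort(raw$accel[window$start:window$end])
  n <- length(srt)
  ref <- srt[ceiling(n / 2)]
  scale <- srt[ceiling(0.9 * n)] - srt[ceiling(0.1 * n)]
  if (!is.finite(scale) || scale <= 0) return(raw)
  retrace(round((raw$accel - ref) / scale * 4096) / 4096, raw)
}

run_template_pipeline <- function(raw, window, config, pre_fraction, tl_fun,
                                  method) {
  raw <- canonicalize_trace(raw, window)
  seg <- segment_trace(raw, window)
  stage <- function(name, expr) {
    tryCatch(expr, stepmatch_error = function(e) {
      abort_stage(conditionMessage(e), class(e)[1], stage = name, parent = e)
    })
  }
  tl <- stage("template_length", tl_fun(seg, config))
  peaks <- stage("template_peaks", find_template_peaks(seg, tl, config))
  sections <- stage("sections", extract_sections(seg, peaks, tl, pre_fraction))
  template <- stage("template", build_template(sections, tl, pre_fraction,
                                               fit = config$template_fit))
  rs <- stage("resegment", resegment(raw, window, tl))
  match <- stage("match", match_signals(rs$trace, template, config))
  sel <- stage("event_peaks", select_event_peaks(
    match$coefficient, tl, window, offset = rs$window$start,
    shift_fraction = pre_fraction, config = config))
  events <- shift_events(sel, tl, pre_fraction, trace_fs(raw), method = method)
  durations <- stage("durations", durations_from_events(events))
  new_step_detection(events, durations, template, tl, match, window,
                     trace_placement(raw))
}

#' Detect steps from a lower-back acceleration trace
#'
#' Runs the full template-match pipeline on a manually segmented lower-back
#' AP acceleration trace: step-cycle template length from the unbiased
#' autocovariance, anchor peaks, DTW-averaged template, resegmentation,
#' sliding match signals, coefficient peak selection and the forward shift
#' by 15 % TL. Each heel strike of either foot yields one event; intervals
#' between events are step durations.
#'
#' @param raw Raw (unsegmented) [accel_trace()] with placement
#'   `"lower_back"`.
#' @param window Manual [seg_window()] from some samples before the first
#'   heel strike to some samples after the last included one.
#' @param config A [detector_config()].
#' @return A `"step_detection"` object: `events` ([event_series()]),
#'   `durations` (tibble of step durations), `template`, `tl`, `match`
#'   (sliding signals tibble), `window`, `placement`.
#' @export
detect_steps_lowback <- function(raw, window, config = detector_config()) {
  run_template_pipeline(raw, window, config,
                        pre_fraction = config$pre_fraction_lowback,
                        tl_fun = template_length_lowback,
                        method = "lowback_accel")
}

#' Detect strides from one heel acceleration trace
#'
#' As [detect_steps_lowback()], but with the stride-cycle template length
#' (autocovariance-peak rule), sections starting 5 % TL before their anchor
#' (heel peaks are steeper and TL about twice as long) and a 5 % TL forward
#' shift. Each heel strike of that foot yields one event; intervals are
#' stride durations.
#'
#' @param raw Raw [accel_trace()] with placement `"heel_left"` or
#'   `"heel_right"`.
#' @inheritParams detect_steps_lowback
#' @return A `"step_detection"` object with stride durations.
#' @export
detect_strides_heel <- function(raw, window, config = detector_config()) {
  method <- switch(trace_placement(raw),
                   heel_left = "heel_accel_left",
                   heel_right = "heel_accel_right",
                   abort_stage("heel detection needs a heel-placed trace",
                               "stepmatch_invalid_input"))
  run_template_pipeline(raw, window, config,
                        pre_fraction = config$pre_fraction_heel,
                        tl_fun = template_length_heel,
                        method = method)
}

#' Detect steps from both heel traces combined
#'
#' Runs [detect_strides_heel()] on each foot and merges the two stride event
#' series with [combine_heel_events()]; intervals of the merged alternating
#' series are step durations.
#'
#' @param left,right Raw heel [accel_trace()]s (placements `"heel_left"`,
#'   `"heel_right"`).
#' @inheritParams detect_steps_lowback
#' @return A list of class `"heel_detection"`: `left`, `right` (per-foot
#'   `"step_detection"`), `events` (combined [event_series()]), `durations`
#'   (step durations tibble).
#' @export
detect_steps_heel <- function(left, right, window, config = detector_config()) {
  dl <- detect_strides_heel(left, window, config)
  dr <- detect_strides_heel(right, window, config)
  combined <- combine_heel_events(dl$events, dr$events)
  durations <- durations_from_events(combined, kind = "step")
  structure(list(left = dl, right = dr, events = combined, durations = durations),
            class = "heel_detection")
}

#' @export
print.heel_detection <- function(x, ...) {
  cat(sprintf("<heel_detection> %d combined events (%d left + %d right strides)\n",
              nrow(x$events), nrow(x$left$events), nrow(x$right$events)))
  cat(sprintf("  mean step duration %.0f ms\n", mean(x$durations$duration_ms)))
  invisible(x)
}

#' Tidy detected events
#'
#' @param x A `"step_detection"` or `"heel_detection"`.
#' @param ... Unused.
#' @return A tibble with one row per detected event: `method`,
#'   `event_index_samples`, `event_time_s`, and `duration_ms` (interval to
#'   the next event, `NA` for the last).
#' @export
tidy.step_detection <- function(x, ...) {
  ev <- x$events
  tibble::tibble(
    method = attr(ev, "method"),
    event_index_samples = ev$event,
    event_time_s = ev$time_s,
    duration_ms = c(x$durations$duration_ms, NA_real_)
  )
}

#' @rdname tidy.step_detection
#' @export
tidy.heel_detection <- function(x, ...) {
  ev <- x$events
  tibble::tibble(
    method = attr(ev, "method"),
    foot = ev$foot,
    event_index_samples = ev$event,
    event_time_s = ev$time_s,
    duration_ms = c(x$durations$duration_ms, NA_real_)
  )
}

#' One-row summary of a detection
#'
#' @param x A `"step_detection"` or `"heel_detection"`.
#' @param ... Unused.
#' @return A one-row tibble: `method`, `n_events`, `tl_samples`,
#'   `dominant_freq_hz`, `mean_duration_ms`, `sd_duration_ms`, `cv_duration`.
#' @export
glance.step_detection <- function(x, ...) {
  d <- x$durations$duration_ms
  tibble::tibble(
    method = attr(x$events, "method"),
    n_events = nrow(x$events),
    tl_samples = x$tl$tl,
    dominant_freq_hz = x$tl$dominant_freq,
    mean_duration_ms = mean(d),
    sd_duration_ms = stats::sd(d),
    cv_duration = stats::sd(d) / mean(d)
  )
}

#' @rdname glance.step_detection
#' @export
glance.heel_detection <- function(x, ...) {
  d <- x$durations$duration_ms
  tibble::tibble(
    method = "heel_accel_combined",
    n_events = nrow(x$events),
    tl_samples = NA_integer_,
    dominant_freq_hz = NA_real_,
    mean_duration_ms = mean(d),
    sd_duration_ms = stats::sd(d),
    cv_duration = stats::sd(d) / mean(d)
  )
}
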